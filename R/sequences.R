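#' Construct a genome sequence object
#'
#' A minimal container for a named nucleotide sequence. Sequences are stored
#' uppercase over the alphabet `{A, C, G, T, N}`; anything else is rejected.
#' All coordinates used by the package are 0-based, half-open; conversion to
#' 1-based happens only at report boundaries.
#'
#' @param id Sequence name (single string).
#' @param seq Nucleotide string; lowercase input is uppercased.
#' @return An object of class `genome_sequence` with fields `id`, `seq`,
#'   `length`.
#' @examples
#' g <- genome_sequence("g", "acgt")
#' g$seq
#' @export
genome_sequence <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) {
    stop("genome sequence '", id, "' is empty")
  }
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("genome sequence '", id, "' contains illegal character(s): '",
         substr(bad, 1L, 10L), "'")
  }
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", x$id, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the `{A, C, G, T, N}`
#' alphabet; an offending record is named in the error message.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [genome_sequence()] objects, in file order.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA file '", path, "' has an empty header")
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- tryCatch(genome_sequence(ids[i], as.character(set[[i]])),
                         error = function(e) {
                           stop("FASTA record '", ids[i], "' in '", path,
                                "': ", conditionMessage(e))
                         })
  }
  names(out) <- ids
  out
}

#' Write genome sequences to a FASTA file
#'
#' @param genomes A [genome_sequence()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Alphabet `{A, C, G, T, N}`; `N` complements to `N`. The empty string maps
#' to itself.
#'
#' @param seq Nucleotide string.
#' @return The reverse complement, same alphabet.
#' @examples
#' revcomp("AAGATTTATCTG")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("illegal character in sequence: '",
         gsub("[ACGTN]", "", seq), "'")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Forward-strand slice [start, end) of a genome, 0-based half-open.
.slice <- function(genome, start, end) {
  substr(genome$seq, start + 1L, end)
}
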