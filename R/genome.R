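# Synthetic genomes ---------------------------------------------------------

#' Generate a random genome with optional planted motifs
#'
#' Bases are i.i.d. at the requested GC content; planted sequences overwrite
#' the random background at the stated (1-based) positions, reverse
#' complemented when planted on the minus strand. The result is a plain
#' character string writable as FASTA with [write_genome_fasta()].
#'
#' @param length_bp Genome length in base pairs (> 0).
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param planted Optional data frame with columns `seq` (character over
#'   ACGT), `pos` (1-based start) and `strand` (`"+"` or `"-"`). Planted
#'   sites must fit inside the genome and must not overlap each other.
#' @param seed Optional integer seed; the genome is reproducible under a
#'   fixed seed.
#' @return A character scalar (the sequence, uppercase ACGT).
#' @export
#' @examples
#' g <- generate_genome(100,
#'   planted = data.frame(
#'     seq = "TCCCTATCAGTGATAGAGA", pos = 50, strand = "+"
#'   ), seed = 1
#' )
#' substr(g, 50, 68)
generate_genome <- function(length_bp, gc = 0.5, planted = NULL,
                            seed = NULL) {
  stopifnot(length_bp >= 1, gc >= 0, gc <= 1)
  run <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(p), length_bp, replace = TRUE, prob = p)
    genome <- paste(bases, collapse = "")
    if (!is.null(planted) && nrow(planted) > 0) {
      planted <- tibble::as_tibble(planted)
      stopifnot(all(c("seq", "pos", "strand") %in% names(planted)))
      planted$seq <- toupper(planted$seq)
      if (any(grepl("[^ACGT]", planted$seq))) {
        stop("planted sequences must be over {A,C,G,T}.", call. = FALSE)
      }
      starts <- planted$pos
      ends <- planted$pos + nchar(planted$seq) - 1
      if (any(starts < 1) || any(ends > length_bp)) {
        stop("planted site falls outside the genome.", call. = FALSE)
      }
      ord <- order(starts)
      if (any(starts[ord][-1] <= ends[ord][-length(ord)])) {
        stop("planted sites overlap.", call. = FALSE)
      }
      for (i in seq_len(nrow(planted))) {
        s <- planted$seq[i]
        if (planted$strand[i] == "-") s <- reverse_complement(s)
        substr(genome, starts[i], ends[i]) <- s
      }
    }
    genome
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Reverse complement of a DNA sequence
#'
#' @param x Character scalar over ACGT (case insensitive).
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write / read genomes as FASTA
#'
#' Thin wrappers around Biostrings FASTA I/O so that synthetic genomes can be
#' exchanged with standard tools.
#'
#' @param genome A named (or unnamed) character vector of sequences; unnamed
#'   sequences are called `chr1`, `chr2`, ...
#' @param path File path.
#' @return `write_genome_fasta()` returns `path` invisibly;
#'   `read_genome_fasta()` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(names(genome))) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
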