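# Contiguous-match motif scanning -------------------------------------------

# Longest run of TRUE in a logical vector (0 if none).
longest_run <- function(m) {
  if (!any(m)) {
    return(0L)
  }
  r <- rle(m)
  max(r$lengths[r$values])
}

#' Scan a genome for contiguous matches to a motif
#'
#' Exhaustive both-strand scan: every genomic window of the motif length is
#' scored by its longest run of consecutive identities to the motif, and
#' windows whose run reaches `min_len` are reported. Each genomic window is
#' reported at most once: when both strands reach `min_len`, the strand with
#' the longer run wins and ties go to plus. This operationalizes sequence
#' "similarity" as contiguous identity length, a deterministic stand-in for
#' seeded local alignment that lets counts-per-alignment-length be compared
#' with analytic random-genome expectations
#' ([expected_match_counts()]).
#'
#' Windows containing ambiguity codes (non-ACGT letters) are skipped; the
#' number of skipped windows per chromosome is returned in the `"skipped"`
#' attribute.
#'
#' @param genome A named character vector of chromosome sequences, a single
#'   sequence, or the path to a FASTA file.
#' @param motif Query motif over `{A,C,G,T}` (e.g. the 19-bp tetO operator
#'   `"TCCCTATCAGTGATAGAGA"`).
#' @param min_len Minimum contiguous identity (bp), `<= nchar(motif)`.
#' @return A tibble with columns `chrom`, `start` (0-based), `end`
#'   (half-open), `strand`, `match_len` (longest contiguous identity) and
#'   `mismatches` (count over the full motif window, on the reported strand),
#'   sorted by chromosome and start. Attribute `"skipped"`: windows skipped
#'   for ambiguity codes.
#' @export
#' @examples
#' g <- generate_genome(2000,
#'   planted = data.frame(
#'     seq = "TCCCTATCAGTGATAGAGA", pos = 1000, strand = "+"
#'   ), seed = 3
#' )
#' scan_contiguous_matches(g, "TCCCTATCAGTGATAGAGA", min_len = 19)
scan_contiguous_matches <- function(genome, motif, min_len) {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) {
    stop("motif must be over {A,C,G,T}.", call. = FALSE)
  }
  L <- nchar(motif)
  stopifnot(min_len >= 1, min_len <= L)
  if (length(genome) == 1L && !grepl("[ACGTNacgtn]{10}", genome) &&
    file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  if (is.null(names(genome))) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  motif_rc <- reverse_complement(motif)
  mot_plus <- strsplit(motif, "")[[1]]
  mot_minus <- strsplit(motif_rc, "")[[1]]

  scan_one <- function(chrom, seq_chr) {
    seq_chr <- toupper(seq_chr)
    G <- nchar(seq_chr)
    n_win <- G - L + 1L
    if (n_win < 1L) {
      return(list(hits = NULL, skipped = 0L))
    }
    subject <- Biostrings::DNAString(seq_chr)
    # candidate windows: exact match of any length-min_len sub-motif
    candidates <- function(m) {
      starts <- integer(0)
      for (j in seq_len(L - min_len + 1L)) {
        sub <- substr(m, j, j + min_len - 1L)
        hits <- Biostrings::start(Biostrings::matchPattern(sub, subject))
        starts <- c(starts, hits - (j - 1L))
      }
      starts <- unique(starts)
      starts[starts >= 1L & starts <= n_win]
    }
    cand <- sort(unique(c(candidates(motif), candidates(motif_rc))))
    # exact count of windows overlapping an ambiguity code
    bad <- gregexpr("[^ACGT]", seq_chr)[[1]]
    skipped <- 0L
    if (bad[1] != -1L) {
      lo <- pmax(bad - L + 1L, 1L)
      hi <- pmin(bad, n_win)
      iv <- cbind(lo, hi)[hi >= lo, , drop = FALSE]
      if (nrow(iv)) {
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        cover <- 0L
        cur_lo <- iv[1, 1]
        cur_hi <- iv[1, 2]
        for (r in seq_len(nrow(iv))[-1]) {
          if (iv[r, 1] > cur_hi + 1L) {
            cover <- cover + (cur_hi - cur_lo + 1L)
            cur_lo <- iv[r, 1]
            cur_hi <- iv[r, 2]
          } else {
            cur_hi <- max(cur_hi, iv[r, 2])
          }
        }
        skipped <- cover + (cur_hi - cur_lo + 1L)
      }
    }
    if (!length(cand)) {
      return(list(hits = NULL, skipped = skipped))
    }
    rows <- purrr::map(cand, function(s) {
      win <- strsplit(substr(seq_chr, s, s + L - 1L), "")[[1]]
      if (any(!win %in% c("A", "C", "G", "T"))) {
        return(NULL)
      }
      mp <- win == mot_plus
      mm <- win == mot_minus
      run_p <- longest_run(mp)
      run_m <- longest_run(mm)
      if (max(run_p, run_m) < min_len) {
        return(NULL)
      }
      if (run_p >= run_m) {
        tibble::tibble(
          chrom = chrom, start = s - 1L, end = s + L - 1L, strand = "+",
          match_len = run_p, mismatches = sum(!mp)
        )
      } else {
        tibble::tibble(
          chrom = chrom, start = s - 1L, end = s + L - 1L, strand = "-",
          match_len = run_m, mismatches = sum(!mm)
        )
      }
    })
    list(hits = purrr::list_rbind(purrr::compact(rows)), skipped = skipped)
  }

  per_chr <- purrr::imap(as.list(genome), function(s, nm) scan_one(nm, s))
  hits <- purrr::list_rbind(purrr::compact(purrr::map(per_chr, "hits")))
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- tibble::tibble(
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), match_len = integer(0), mismatches = integer(0)
    )
  }
  hits <- dplyr::arrange(hits, .data$chrom, .data$start)
  attr(hits, "skipped") <- sum(vapply(per_chr, `[[`, integer(1), "skipped"))
  hits
}

#' Cumulative hit counts by alignment length
#'
#' Counts scanned sites whose longest contiguous identity is at least each
#' requested length; the census grows roughly four-fold per base pair removed,
#' mirroring the exponential growth of quasi-consensus sites at shorter
#' alignment lengths.
#'
#' @param hits Output of [scan_contiguous_matches()].
#' @param lengths Integer vector of alignment lengths; defaults to the range
#'   of observed `match_len`.
#' @return A tibble with columns `min_len` and `n_sites` (count of hits with
#'   `match_len >= min_len`), non-increasing in `min_len`.
#' @export
count_by_alignment_length <- function(hits, lengths = NULL) {
  stopifnot(is.data.frame(hits), "match_len" %in% names(hits))
  if (is.null(lengths)) {
    lengths <- if (nrow(hits)) {
      seq(min(hits$match_len), max(hits$match_len))
    } else {
      integer(0)
    }
  }
  tibble::tibble(
    min_len = as.integer(lengths),
    n_sites = vapply(
      lengths, function(l) sum(hits$match_len >= l), numeric(1)
    )
  )
}

#' Per-mismatch tally of scanned sites
#'
#' @param hits Output of [scan_contiguous_matches()].
#' @return A tibble with columns `mismatches` and `n_sites`.
#' @export
count_by_mismatches <- function(hits) {
  stopifnot(is.data.frame(hits), "mismatches" %in% names(hits))
  dplyr::count(hits, .data$mismatches, name = "n_sites")
}

#' Expected contiguous-match counts in a random genome
#'
#' Analytic expectation of the number of genomic windows (both strands of a
#' uniform-base genome) whose longest contiguous identity to an `motif_len`-bp
#' motif is at least `ell`. A window has such a run if, for some offset `j`,
#' a maximal run of matches starts at motif position `j` and extends `>= ell`:
#' the run start requires a preceding mismatch (probability 3/4) except at
#' `j = 1`, and the run itself has probability `4^-ell`. Summing over the
#' `motif_len - ell + 1` admissible offsets gives, per window and strand,
#' `4^-ell * (1 + (motif_len - ell) * 3/4)`; multiple qualifying runs in one
#' window are a negligible higher-order correction. With `G - motif_len + 1`
#' windows per strand:
#' `E(ell) = 2 * (G - motif_len + 1) * 4^-ell * (1 + (motif_len - ell) * 3/4)`.
#'
#' @param genome_bp Genome length `G` (bp).
#' @param motif_len Motif length `L` (bp).
#' @param lengths Alignment lengths `ell` (vector, each `<= motif_len`).
#' @return A tibble with columns `min_len` and `expected` (expected
#'   cumulative hit count).
#' @export
#' @examples
#' expected_match_counts(1e7, 19, 9:12)
expected_match_counts <- function(genome_bp, motif_len, lengths) {
  stopifnot(all(lengths >= 1), all(lengths <= motif_len))
  n_win <- pmax(genome_bp - motif_len + 1, 0)
  expected <- 2 * n_win * 4^(-lengths) * (1 + (motif_len - lengths) * 3 / 4)
  tibble::tibble(min_len = as.integer(lengths), expected = expected)
}
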