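# Microsatellite (SSR) mining: perfect di-/tri-/tetranucleotide tandem
# repeats with motif canonicalization into strand/rotation families.

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                       "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i) {
    paste0(substr(m, i, k), substr(m, 1, i - 1))
  }, character(1))
}

is_power_of_shorter <- function(m) {
  k <- nchar(m)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0L && strrep(substr(m, 1, d), k / d) == m) return(TRUE)
  }
  FALSE
}

#' Canonicalize an SSR motif into its strand/rotation family
#'
#' Two tracts belong to the same family when their motifs are rotations
#' of each other or of each other's reverse complement (an AG repeat read
#' on the opposite strand is a CT repeat). The canonical representative
#' is the lexicographically smallest string among all rotations of the
#' motif and of its reverse complement; the family label is
#' \code{"CANONICAL/REVCOMP"} (e.g. \code{AG/CT}). Motifs that are whole
#' powers of a shorter unit (AA, ATAT, ...) are rejected: they describe a
#' shorter-motif repeat, and mononucleotide runs are never reported.
#'
#' @param raw Motif string, 2-4 bases over \{A,C,G,T\}.
#' @return A list with \code{canonical}, \code{family} and \code{klass}
#'   (\code{"di"}, \code{"tri"} or \code{"tetra"}), or \code{NULL} if the
#'   motif is rejected (power of a shorter unit, or contains non-ACGT).
#' @examples
#' canonical_motif("CT")    # AG/CT family
#' canonical_motif("ATAT")  # NULL: power of AT
#' @export
canonical_motif <- function(raw) {
  raw <- toupper(raw)
  if (nchar(raw) < 2L || nchar(raw) > 4L) {
    stop("motif length must be 2-4, got '", raw, "'")
  }
  if (!grepl("^[ACGT]+$", raw)) return(NULL)
  if (is_power_of_shorter(raw)) return(NULL)
  cands <- c(rotations(raw), rotations(revcomp_chr(raw)))
  canonical <- min(cands)
  list(canonical = canonical,
       family = paste0(canonical, "/", revcomp_chr(canonical)),
       klass = c("2" = "di", "3" = "tri", "4" = "tetra")[[as.character(nchar(raw))]])
}

ssr_empty <- function() {
  data.frame(transcript_id = character(0), start = integer(0),
             end = integer(0), motif = character(0), family = character(0),
             klass = character(0), repeat_count = integer(0),
             tract_length = integer(0), stringsAsFactors = FALSE)
}

# Maximal perfect tandem tracts of period k in a character vector.
# Returns 0-based spans trimmed to complete motif copies.
find_tracts_period <- function(x, k, min_copies) {
  n <- length(x)
  if (n < (min_copies) * k) return(NULL)
  ok <- x %in% c("A", "C", "G", "T")
  i1 <- seq_len(n - k)
  eq <- (x[i1] == x[i1 + k]) & ok[i1] & ok[i1 + k]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= (min_copies - 1L) * k
  if (!any(keep)) return(NULL)
  res <- lapply(which(keep), function(j) {
    a <- starts[j]; L <- r$lengths[j]
    copies <- L %/% k + 1L
    unit <- paste(x[a:(a + k - 1L)], collapse = "")
    if (any(!ok[a:(a + k - 1L)]) || is_power_of_shorter(unit)) return(NULL)
    # 0-based half-open span over complete copies, anchored leftmost
    data.frame(start = a - 1L, end = a - 1L + copies * k, unit = unit,
               repeat_count = copies, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) NULL else do.call(rbind, res)
}

#' Find perfect microsatellites in transcript sequences
#'
#' Scans for maximal perfect tandem tracts of di-, tri- and
#' tetranucleotide motifs made of complete copies, with per-class
#' minimum repeat counts (defaults: di >= 9, tri >= 6, tetra >= 4, so the
#' shortest reportable tract is 16 nt). Tracts are broken at N. When
#' tracts of different classes overlap, the longer tract wins; on a tie
#' the smaller motif class wins — one hit per locus.
#'
#' @param seqs Named \code{DNAStringSet} or named character vector.
#' @param min_di,min_tri,min_tetra Minimum complete motif copies per class.
#' @return data.frame with \code{transcript_id, start, end} (0-based
#'   half-open), \code{motif} (canonical), \code{family}, \code{klass},
#'   \code{repeat_count, tract_length}, sorted by (transcript, start).
#' @export
find_ssrs <- function(seqs, min_di = 9L, min_tri = 6L, min_tetra = 4L) {
  min_di <- unname(as.integer(min_di)); min_tri <- unname(as.integer(min_tri))
  min_tetra <- unname(as.integer(min_tetra))
  stopifnot(min_di >= 1L, min_tri >= 1L, min_tetra >= 1L)
  if (!is.character(seqs)) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  thr <- c(`2` = min_di, `3` = min_tri, `4` = min_tetra)
  out <- lapply(names(seqs), function(id) {
    x <- strsplit(toupper(seqs[[id]]), "")[[1]]
    cand <- lapply(2:4, function(k) {
      tr <- find_tracts_period(x, k, thr[[as.character(k)]])
      if (is.null(tr)) return(NULL)
      tr$k <- k
      tr
    })
    cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    cand$tract_length <- cand$end - cand$start
    # one hit per locus: longer tract wins; tie -> smaller motif class
    ord <- order(-cand$tract_length, cand$k, cand$start)
    cand <- cand[ord, , drop = FALSE]
    sel <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!any(sel & cand$start < cand$end[i] & cand$end > cand$start[i])) {
        sel[i] <- TRUE
      }
    }
    cand <- cand[sel, , drop = FALSE]
    fam <- lapply(cand$unit, canonical_motif)
    data.frame(
      transcript_id = id, start = cand$start, end = cand$end,
      motif = vapply(fam, `[[`, character(1), "canonical"),
      family = vapply(fam, `[[`, character(1), "family"),
      klass = vapply(fam, `[[`, character(1), "klass"),
      repeat_count = cand$repeat_count, tract_length = cand$tract_length,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(ssr_empty())
  out <- out[order(match(out$transcript_id, names(seqs)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize SSR hits by motif family
#'
#' Per-class totals, per-family counts with percentage of their class,
#' and the count/percentage of unigenes carrying at least one SSR.
#' Percentages are reported to one decimal.
#'
#' @param hits SSR hit frame from \code{\link{find_ssrs}}.
#' @param unigene_count Number of unigenes scanned (denominator for the
#'   unigenes-with-SSR percentage); must be positive.
#' @param mode Rounding mode for printed percentages (see
#'   \code{\link{percent_1dp}}).
#' @return list with \code{by_family} (klass, family, n, pct_of_class),
#'   \code{by_class} (klass, n, pct_of_total), \code{total},
#'   \code{unigenes_with_ssr} and \code{pct_unigenes_with_ssr}.
#' @export
summarize_motifs <- function(hits, unigene_count, mode = "round") {
  if (unigene_count <= 0L) stop("unigene_count must be positive")
  klasses <- c("di", "tri", "tetra")
  total <- nrow(hits)
  by_class <- data.frame(
    klass = klasses,
    n = vapply(klasses, function(k) sum(hits$klass == k), integer(1)),
    stringsAsFactors = FALSE)
  by_class$pct_of_total <- if (total > 0) {
    percent_1dp(by_class$n, total, mode)
  } else rep(NA_real_, 3L)
  fam <- lapply(klasses, function(k) {
    h <- hits[hits$klass == k, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    tb <- sort(table(h$family), decreasing = TRUE)
    data.frame(klass = k, family = names(tb), n = as.integer(tb),
               pct_of_class = percent_1dp(as.integer(tb), nrow(h), mode),
               stringsAsFactors = FALSE)
  })
  fam <- do.call(rbind, fam[!vapply(fam, is.null, logical(1))])
  if (is.null(fam)) {
    fam <- data.frame(klass = character(0), family = character(0),
                      n = integer(0), pct_of_class = numeric(0))
  }
  n_uni <- length(unique(hits$transcript_id))
  list(by_family = fam, by_class = by_class, total = total,
       unigenes_with_ssr = n_uni,
       pct_unigenes_with_ssr = percent_1dp(n_uni, unigene_count, mode))
}
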