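# Independent brute-force oracles. These deliberately reimplement the
# scans from first principles (substring enumeration, pairwise loops,
# manual IUPAC digestion) so the package's vectorized/regex paths are
# checked against a second route.

oracle_is_power <- function(m) {
  k <- nchar(m)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && paste(rep(substr(m, 1L, d), k / d), collapse = "") == m)
      return(TRUE)
  }
  FALSE
}

# brute-force SSR scan: enumerate every (start, motif length), count
# complete copies, keep left-maximal candidates meeting the threshold,
# then resolve overlaps with the same one-hit-per-locus rule.
oracle_find_ssrs <- function(seq, min_di = 9L, min_tri = 6L, min_tetra = 4L) {
  thr <- c(`2` = min_di, `3` = min_tri, `4` = min_tetra)
  n <- nchar(seq)
  cand <- list()
  for (k in 2:4) {
    for (st in seq_len(max(0L, n - k + 1L))) {
      unit <- substr(seq, st, st + k - 1L)
      if (!grepl("^[ACGT]+$", unit) || oracle_is_power(unit)) next
      # left-maximal: no complete copy immediately before
      if (st - k >= 1L && substr(seq, st - k, st - 1L) == unit) next
      copies <- 1L
      while (st + copies * k + k - 1L <= n &&
             substr(seq, st + copies * k, st + copies * k + k - 1L) == unit) {
        copies <- copies + 1L
      }
      if (copies >= thr[[as.character(k)]]) {
        cand[[length(cand) + 1L]] <-
          data.frame(start = st - 1L, end = st - 1L + copies * k, k = k,
                     len = copies * k, repeat_count = copies, unit = unit,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), k = integer(0),
                      repeat_count = integer(0), unit = character(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$len, cand$k, cand$start), , drop = FALSE]
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(sel & cand$start < cand$end[i] & cand$end > cand$start[i]))
      sel[i] <- TRUE
  }
  out <- cand[sel, c("start", "end", "k", "repeat_count", "unit")]
  out[order(out$start), , drop = FALSE]
}

# exhaustive pairwise / edge / sliding-window scans
oracle_cs <- function(pos, threshold = 60L) {
  vapply(seq_along(pos), function(i) {
    any(abs(pos[-i] - pos[i]) < threshold)
  }, logical(1))
}

oracle_cl <- function(pos, len, threshold = 60L) {
  vapply(pos, function(p) min(p, len - 1L - p) < threshold, logical(1))
}

oracle_hv <- function(pos, window = 100L, max_snvs = 5L) {
  # every possible window start; flag members of any over-full window
  vapply(seq_along(pos), function(i) {
    for (w0 in (pos[i] - window + 1L):pos[i]) {
      if (sum(pos >= w0 & pos < w0 + window) > max_snvs) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# manual IUPAC digestion: match table lookup position by position, cut at
# every site start on either strand, compare fragment-length multisets
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_site_starts <- function(site, subject) {
  sch <- strsplit(site, "")[[1]]
  x <- strsplit(subject, "")[[1]]
  L <- length(sch)
  hits <- integer(0)
  if (length(x) < L) return(hits)
  for (p in seq_len(length(x) - L + 1L)) {
    if (all(mapply(function(a, b) a %in% oracle_iupac[[b]],
                   x[p:(p + L - 1L)], sch))) {
      hits <- c(hits, p)
    }
  }
  hits
}

oracle_digest <- function(site, subject) {
  cuts <- oracle_site_starts(site, subject)
  rc <- oracle_revcomp(site)
  if (rc != site) cuts <- c(cuts, oracle_site_starts(rc, subject))
  cuts <- sort(unique(cuts))
  sort(diff(c(0L, cuts, nchar(subject) + 1L)))
}

oracle_context <- function(seq, pos, ref, alt, flank = 60L) {
  n <- nchar(seq)
  left <- substr(seq, max(1L, pos + 1L - flank), pos)
  rs <- pos + 1L + nchar(ref)
  right <- if (rs > n) "" else substr(seq, rs, min(n, pos + nchar(ref) + flank))
  list(ref = paste0(left, ref, right), alt = paste0(left, alt, right))
}

oracle_cef <- function(seq, pos, ref, alts, enzymes, flank = 60L) {
  for (a in alts) {
    ctx <- oracle_context(seq, pos, ref, a, flank)
    for (j in seq_len(nrow(enzymes))) {
      if (!identical(oracle_digest(enzymes$site[j], ctx$ref),
                     oracle_digest(enzymes$site[j], ctx$alt))) return(TRUE)
    }
  }
  FALSE
}

# ---- small fixture builders -----------------------------------------

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# variant frame from bare positions on one transcript (all ref A, alt G)
toy_variants <- function(pos, tid = "t1", ref = "A", alt = "G",
                         gts = NULL, samples = c("S1")) {
  v <- data.frame(transcript_id = tid, pos = as.integer(pos), ref = ref,
                  alt = alt, stringsAsFactors = FALSE)
  for (s in samples) v[[s]] <- if (is.null(gts)) "0/1" else gts
  attr(v, "samples") <- samples
  v
}

toy_panel <- function(species = c("AET", "INC", "MEL", "TOR")) {
  data.frame(sample_id = species, species_id = species,
             stringsAsFactors = FALSE)
}

# variant frame with one sample per species and given per-species GTs
panel_variants <- function(gt, tid = "t1", pos = 100L, ref = "A",
                           alt = "G") {
  v <- data.frame(transcript_id = tid, pos = as.integer(pos), ref = ref,
                  alt = alt, stringsAsFactors = FALSE)
  for (sp in names(gt)) v[[sp]] <- gt[[sp]]
  attr(v, "samples") <- names(gt)
  v
}
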