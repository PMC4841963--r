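# Seeded simulator: transcripts with ORFs, planted perfect SSR tracts,
# and a multi-species VCF with planted heterozygous (intraspecific) and
# homozygous-differential (interspecific) SNPs/INDELs, plus a truth
# table recording every planted feature and its intended classification
# and filter outcome. Background sequence is rejection-sampled so the
# only SSRs meeting the mining thresholds are the planted ones.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulation parameters
#'
#' Defaults describe the closed-loop validation world: 200 transcripts of
#' 300-3,000 nt, about 45% carrying an ORF, ~0.6 planted SSRs per
#' transcript, ~1.2 SNPs and ~0.25 INDELs per kb of well-spaced "clean"
#' variants, and per-transcript probabilities of deliberately planting a
#' close SNV pair (CS60 violation), a near-edge variant (CL60), a dense
#' 6-variant cluster (HV0.05) and, for half the clean SNPs, a restriction
#' site whose alt allele destroys it (CAPS/CEF). Heterozygosity weights
#' set how often a planted variant is intraspecific in each species.
#'
#' @param n_transcripts Number of transcripts.
#' @param len_min,len_max Transcript length range in nt (min >= 50).
#' @param orf_fraction Probability a transcript carries an ORF.
#' @param ssr_plant_rate Expected planted SSRs per transcript (Poisson).
#' @param snp_rate,indel_rate Expected clean variants per kb.
#' @param species Species identifiers.
#' @param heterozygosity Named per-species weights: probability mass that
#'   a planted variant is heterozygous (intraspecific) in that species;
#'   the remainder of the mass yields interspecific patterns.
#' @param p_cs_pair,p_cl_edge,p_hv_cluster Per-transcript probabilities
#'   of planting each violation construct.
#' @param caps_fraction Fraction of clean SNPs given a planted
#'   differential restriction site.
#' @param samples_per_species Samples per species in the emitted VCF.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(n_transcripts = 200L, len_min = 300L, len_max = 3000L,
                       orf_fraction = 0.45, ssr_plant_rate = 0.8,
                       snp_rate = 1.2, indel_rate = 0.25,
                       species = c("AET", "INC", "MEL", "TOR"),
                       heterozygosity = c(AET = 0.40, INC = 0.08,
                                          MEL = 0.02, TOR = 0.15),
                       p_cs_pair = 0.15, p_cl_edge = 0.10,
                       p_hv_cluster = 0.06, caps_fraction = 0.5,
                       samples_per_species = 1L, seed = 1L) {
  stopifnot(len_min >= 50L, len_min <= len_max, n_transcripts >= 1L,
            ssr_plant_rate >= 0, snp_rate >= 0, indel_rate >= 0,
            all(heterozygosity >= 0), sum(heterozygosity) <= 1,
            setequal(names(heterozygosity), species))
  p <- list(n_transcripts = as.integer(n_transcripts),
            len_min = as.integer(len_min), len_max = as.integer(len_max),
            orf_fraction = orf_fraction, ssr_plant_rate = ssr_plant_rate,
            snp_rate = snp_rate, indel_rate = indel_rate,
            species = sort(species),
            heterozygosity = heterozygosity[sort(species)],
            p_cs_pair = p_cs_pair, p_cl_edge = p_cl_edge,
            p_hv_cluster = p_hv_cluster, caps_fraction = caps_fraction,
            samples_per_species = as.integer(samples_per_species),
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# non-power motif unit of length k
random_unit <- function(k) {
  repeat {
    u <- random_dna(k)
    if (!is_power_of_shorter(u)) return(u)
  }
}

iupac_classes <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# generator-side IUPAC site matcher and digestion pattern: a deliberate,
# plain-R second route kept apart from the Biostrings-backed filter code
sim_site_starts <- function(site, subject) {
  sch <- strsplit(site, "")[[1]]
  x <- strsplit(subject, "")[[1]]
  L <- length(sch); n <- length(x)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(x[p + j - 1L] %in% iupac_classes[[sch[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

sim_fragments <- function(site, subject) {
  rc <- revcomp_chr(site)
  cuts <- sim_site_starts(site, subject)
  if (rc != site) cuts <- c(cuts, sim_site_starts(rc, subject))
  cuts <- sort(unique(cuts))
  sort(diff(c(0L, cuts, nchar(subject) + 1L)))
}

sim_cef <- function(seq, pos, ref, alts, enzymes, flank = 60L) {
  for (a in alts) {
    ctx <- allele_contexts(seq, pos, ref, a, flank)
    for (j in seq_len(nrow(enzymes))) {
      if (!identical(sim_fragments(enzymes$site[j], ctx$ref),
                     sim_fragments(enzymes$site[j], ctx$alt))) return(TRUE)
    }
  }
  FALSE
}

#' Plant a CAPS-differential restriction site at a position
#'
#' Writes a concrete instance of the enzyme's recognition site into the
#' transcript so that it covers \code{pos}, then picks an alt base at
#' \code{pos} outside the site's IUPAC class there, so exactly the REF
#' allelic context carries the site and the two alleles digest
#' differently. Requires >= 60 nt of flank on both sides.
#'
#' @param seq Transcript sequence (character).
#' @param enzyme One-row data.frame (or list) with \code{name} and
#'   \code{site}.
#' @param pos 0-based variant position.
#' @param enzymes Full catalogue used to verify the differential digest
#'   (other catalogue enzymes may cut too; only the digest difference
#'   matters). Defaults to the packaged catalogue.
#' @return list with \code{seq} (modified), \code{pos}, \code{ref},
#'   \code{alt}, \code{enzyme}.
#' @export
plant_caps_site <- function(seq, enzyme, pos, enzymes = read_enzymes()) {
  L <- nchar(enzyme$site)
  n <- nchar(seq)
  if (pos < 60L || pos > n - 61L) stop("pos must leave >= 60 nt flanks")
  sch <- strsplit(enzyme$site, "")[[1]]
  for (o in sample(seq_len(L)) - 1L) {          # site offset covering pos
    cls <- iupac_classes[[sch[o + 1L]]]
    alt_cands <- setdiff(c("A", "C", "G", "T"), cls)
    if (length(alt_cands) == 0L) next           # N position: cannot break
    if (pos - o < 0L || pos - o + L > n) next
    inst <- vapply(sch, function(ch) {
      cl <- iupac_classes[[ch]]
      if (length(cl) == 1L) cl else sample(cl, 1L)
    }, character(1))
    new_seq <- seq
    substr(new_seq, pos - o + 1L, pos - o + L) <- paste(inst, collapse = "")
    ref <- inst[o + 1L]
    alt <- if (length(alt_cands) == 1L) alt_cands else sample(alt_cands, 1L)
    if (sim_cef(new_seq, pos, ref, alt, enzymes)) {
      return(list(seq = new_seq, pos = pos, ref = ref, alt = alt,
                  enzyme = enzyme$name))
    }
  }
  stop("enzyme site unplaceable at pos ", pos, " for ", enzyme$name)
}

# draw a genotype pattern for one planted variant; returns list(gt =
# named chr per species, intra, inter) with truth tags derived by
# subset enumeration over the drawn per-species alleles
draw_pattern <- function(species, het_w, n_alts) {
  p_intra <- sum(het_w)
  gt <- stats::setNames(rep("0/0", length(species)), species)
  if (stats::runif(1) < p_intra) {
    sp <- sample(species, 1L, prob = het_w / p_intra)
    gt[sp] <- "0/1"
  } else {
    m <- sample.int(length(species) - 1L, 1L)   # how many carry an alt
    carriers <- sample(species, m)
    al <- if (n_alts > 1L && stats::runif(1) < 0.3) "2" else "1"
    gt[carriers] <- paste0(al, "/", al)
    if (stats::runif(1) < 0.20) gt[sample(species, 1L)] <- "./."
    if (stats::runif(1) < 0.10) gt[sample(species, 1L)] <- "0/1"
  }
  # truth tags by enumeration
  parsed <- lapply(gt, function(g) strsplit(g, "/", fixed = TRUE)[[1]])
  is_het <- vapply(parsed, function(a) !any(a == ".") && a[1] != a[2], logical(1))
  is_hom <- vapply(parsed, function(a) !any(a == ".") && a[1] == a[2], logical(1))
  hom_al <- ifelse(is_hom, vapply(parsed, `[`, character(1), 1), NA)
  combos <- character(0)
  for (k in 2:length(species)) {
    for (sub in utils::combn(species, k, simplify = FALSE)) {
      if (all(is_hom[sub]) && length(unique(hom_al[sub])) >= 2L) {
        combos <- c(combos, paste(sub, collapse = "+"))
      }
    }
  }
  list(gt = gt, intra = paste(species[is_het], collapse = ","),
       inter = paste(combos, collapse = ";"))
}

# one transcript's worth of simulation; NULL on (rare) rejection failure
sim_one_transcript <- function(tid, p, enzymes, thr = c(di = 9L, tri = 6L,
                                                        tetra = 4L)) {
  len <- sample(p$len_min:p$len_max, 1L)
  seq <- NULL
  for (attempt in 1:100) {
    cand <- random_dna(len)
    h <- find_ssrs(stats::setNames(cand, tid), thr["di"], thr["tri"], thr["tetra"])
    if (nrow(h) == 0L) { seq <- cand; break }
  }
  if (is.null(seq)) stop("background rejection sampling failed for ", tid)

  # --- plant SSRs ------------------------------------------------------
  n_ssr <- stats::rpois(1L, p$ssr_plant_rate)
  occupied <- matrix(integer(0), ncol = 2)  # 0-based [start,end) + margin
  ssrs <- list()
  for (s in seq_len(n_ssr)) {
    k <- sample(c(2L, 3L, 4L), 1L, prob = c(0.27, 0.63, 0.10))
    copies <- thr[[c("di", "tri", "tetra")[k - 1L]]] + sample(0:6, 1L)
    tract <- strrep(random_unit(k), copies)
    tl <- nchar(tract)
    for (try in 1:30) {
      st <- sample(5:(len - tl - 5L), 1L)
      if (nrow(occupied) == 0L ||
          all(st + tl + 5L <= occupied[, 1] | st - 5L >= occupied[, 2])) {
        substr(seq, st + 1L, st + tl) <- tract
        occupied <- rbind(occupied, c(st, st + tl))
        ssrs[[length(ssrs) + 1L]] <- list(start = st, end = st + tl)
        break
      }
    }
  }
  found <- find_ssrs(stats::setNames(seq, tid), thr["di"], thr["tri"], thr["tetra"])
  planted_spans <- if (length(ssrs)) {
    do.call(rbind, lapply(ssrs, function(s) c(s$start, s$end)))
  } else matrix(integer(0), ncol = 2)
  ok <- nrow(found) == nrow(planted_spans) &&
    (nrow(found) == 0L ||
       all(found[order(found$start), c("start", "end")] ==
             planted_spans[order(planted_spans[, 1]), , drop = FALSE]))
  if (!ok) return(NULL)  # planting collided; caller retries

  # --- ORF -------------------------------------------------------------
  orf <- NULL
  if (stats::runif(1) < p$orf_fraction && len >= 150L) {
    os <- sample(0:(len %/% 3L), 1L)
    oe <- sample(((2L * len) %/% 3L):len, 1L)
    orf <- list(start = os, end = oe, strand = sample(c("+", "-"), 1L))
  }

  # --- plan variant positions -----------------------------------------
  pos_all <- integer(0)
  place <- function(lo, hi, min_gap, tries = 40L) {
    for (t in seq_len(tries)) {
      cand <- sample(lo:hi, 1L)
      if (length(pos_all) == 0L || all(abs(pos_all - cand) >= min_gap)) {
        return(cand)
      }
    }
    NA_integer_
  }
  vars <- list()
  add_var <- function(pos, kind, group) {
    vars[[length(vars) + 1L]] <<- list(pos = pos, kind = kind, group = group)
    pos_all <<- c(pos_all, pos)
  }
  n_clean <- stats::rpois(1L, (p$snp_rate + p$indel_rate) * len / 1000)
  p_indel <- p$indel_rate / (p$snp_rate + p$indel_rate)
  if (len >= 300L) {
    for (i in seq_len(n_clean)) {
      pos <- place(64L, len - 65L, 60L)
      if (!is.na(pos)) {
        add_var(pos, if (stats::runif(1) < p_indel) "INDEL" else "SNP", "clean")
      }
    }
    if (stats::runif(1) < p$p_cs_pair) {
      a <- place(64L, len - 130L, 130L)
      if (!is.na(a)) {
        d <- sample(20:59, 1L)
        add_var(a, "SNP", "cs_pair"); add_var(a + d, "SNP", "cs_pair")
      }
    }
    if (stats::runif(1) < p$p_cl_edge) {
      side <- sample(c("L", "R"), 1L)
      pos <- if (side == "L") place(4L, 55L, 60L) else place(len - 56L, len - 5L, 60L)
      if (!is.na(pos)) add_var(pos, "SNP", "cl_edge")
    }
    if (stats::runif(1) < p$p_hv_cluster && len >= 500L) {
      a <- place(64L, len - 160L, 160L)
      if (!is.na(a)) {
        offs <- sort(sample(seq(0L, 90L, by = 4L), 6L))
        for (o in offs) add_var(a + o, "SNP", "hv_cluster")
      }
    }
  }
  if (length(vars) == 0L) {
    return(list(seq = seq, orf = orf, ssrs = ssrs, vars = list()))
  }

  # --- CAPS planting (edits the sequence; SSR scan re-checked after) ---
  clean_snps <- which(vapply(vars, function(v)
    v$group == "clean" && v$kind == "SNP", logical(1)))
  caps_idx <- clean_snps[stats::runif(length(clean_snps)) < p$caps_fraction]
  for (i in caps_idx) {
    pos <- vars[[i]]$pos
    near_ssr <- nrow(planted_spans) > 0L &&
      any(pos + 8L > planted_spans[, 1] & pos - 8L < planted_spans[, 2])
    if (near_ssr) next
    enzyme <- enzymes[sample.int(nrow(enzymes), 1L), ]
    res <- tryCatch(plant_caps_site(seq, enzyme, pos, enzymes),
                    error = function(e) NULL)
    if (!is.null(res)) {
      seq <- res$seq
      vars[[i]]$ref <- res$ref
      vars[[i]]$alt <- res$alt
      vars[[i]]$group <- "caps"
    }
  }
  found <- find_ssrs(stats::setNames(seq, tid), thr["di"], thr["tri"], thr["tetra"])
  ok <- nrow(found) == nrow(planted_spans) &&
    (nrow(found) == 0L ||
       all(found[order(found$start), c("start", "end")] ==
             planted_spans[order(planted_spans[, 1]), , drop = FALSE]))
  if (!ok) return(NULL)

  # --- alleles ---------------------------------------------------------
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    if (!is.null(v$ref)) next  # caps: already set
    base <- substr(seq, v$pos + 1L, v$pos + 1L)
    if (v$kind == "SNP") {
      vars[[i]]$ref <- base
      vars[[i]]$alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    } else if (stats::runif(1) < 0.5) {  # insertion
      vars[[i]]$ref <- base
      vars[[i]]$alt <- paste0(base, random_dna(sample(1:3, 1L)))
    } else {                             # deletion
      dl <- sample(1:3, 1L)
      vars[[i]]$ref <- substr(seq, v$pos + 1L, v$pos + 1L + dl)
      vars[[i]]$alt <- base
    }
  }
  # occasional second ALT on clean SNPs (multi-allelic sites)
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    if (v$kind == "SNP" && v$group == "clean" && stats::runif(1) < 0.08) {
      extra <- setdiff(c("A", "C", "G", "T"), c(v$ref, v$alt))
      vars[[i]]$alt <- paste(c(v$alt, sample(extra, 1L)), collapse = ",")
    }
  }
  list(seq = seq, orf = orf, ssrs = ssrs, vars = vars)
}

sim_localize <- function(start, end, orf) {
  if (is.null(orf)) return("OTHER")
  if (start >= orf$start && end <= orf$end) return("ORF")
  if (end <= orf$start) return(if (orf$strand == "+") "FIVE_UTR" else "THREE_UTR")
  if (start >= orf$end) return(if (orf$strand == "+") "THREE_UTR" else "FIVE_UTR")
  "OTHER"
}

#' Simulate a transcriptome marker-discovery dataset with ground truth
#'
#' Produces transcripts (FASTA-ready), ORF annotations, a multi-species
#' variant frame (VCF-ready) and a truth table holding every planted SSR
#' (exact span, motif family, localization) and every planted variant
#' (kind, intraspecific/interspecific tags derived from the emitted
#' genotypes by subset enumeration, and the intended outcome of each
#' suitability filter, computed on the final sequences by independent
#' generator-side scans). With a fixed seed all outputs are
#' byte-identical across runs.
#'
#' @param params \code{\link{sim_params}} object.
#' @param out_dir Optional directory: writes \code{transcripts.fasta},
#'   \code{orfs.bed}, \code{variants.vcf}, \code{panel.tsv},
#'   \code{truth_ssrs.tsv}, \code{truth_variants.tsv}.
#' @param enzymes Enzyme catalogue used for CAPS planting and truth CEF.
#' @return list with \code{transcripts} (DNAStringSet), \code{orfs},
#'   \code{variants} (variant frame), \code{panel}, \code{truth}
#'   (list of \code{ssrs} and \code{variants} data.frames), \code{params}.
#' @export
simulate_dataset <- function(params = sim_params(), out_dir = NULL,
                             enzymes = read_enzymes()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    ids <- sprintf("TR%04d", seq_len(params$n_transcripts))
    tr <- vector("list", params$n_transcripts)
    for (i in seq_along(ids)) {
      res <- NULL
      for (attempt in 1:25) {
        res <- sim_one_transcript(ids[i], params, enzymes)
        if (!is.null(res)) break
      }
      if (is.null(res)) stop("simulation failed to converge for ", ids[i])
      tr[[i]] <- res
    }
    names(tr) <- ids

    seqs <- Biostrings::DNAStringSet(vapply(tr, `[[`, character(1), "seq"))
    orf_rows <- lapply(ids, function(id) {
      o <- tr[[id]]$orf
      if (is.null(o)) return(NULL)
      data.frame(transcript_id = id, start = o$start, end = o$end,
                 strand = o$strand, stringsAsFactors = FALSE)
    })
    orfs <- do.call(rbind, orf_rows[!vapply(orf_rows, is.null, logical(1))])
    if (is.null(orfs)) {
      orfs <- data.frame(transcript_id = character(0), start = integer(0),
                         end = integer(0), strand = character(0))
    }

    panel <- do.call(rbind, lapply(params$species, function(sp) {
      data.frame(
        sample_id = if (params$samples_per_species == 1L) sp else
          paste0(sp, "_", seq_len(params$samples_per_species)),
        species_id = sp, stringsAsFactors = FALSE)
    }))

    # truth: SSRs
    truth_ssr_rows <- lapply(ids, function(id) {
      ss <- tr[[id]]$ssrs
      if (length(ss) == 0L) return(NULL)
      do.call(rbind, lapply(ss, function(s) {
        tract <- substr(tr[[id]]$seq, s$start + 1L, s$end)
        unit_len <- (s$end - s$start)
        # recover unit length from the planted tract by smallest period
        k <- 2L
        while (k <= 4L) {
          u <- substr(tract, 1L, k)
          if (unit_len %% k == 0L && strrep(u, unit_len %/% k) == tract) break
          k <- k + 1L
        }
        fam <- canonical_motif(substr(tract, 1L, k))
        data.frame(transcript_id = id, start = s$start, end = s$end,
                   motif = fam$canonical, family = fam$family,
                   klass = fam$klass, repeat_count = unit_len %/% k,
                   tract_length = unit_len,
                   localization = sim_localize(s$start, s$end, tr[[id]]$orf),
                   stringsAsFactors = FALSE)
      }))
    })
    truth_ssr_rows <- truth_ssr_rows[!vapply(truth_ssr_rows, is.null,
                                             logical(1))]
    truth_ssrs <- if (length(truth_ssr_rows) > 0L) {
      r <- do.call(rbind, truth_ssr_rows); rownames(r) <- NULL; r
    } else {
      cbind(ssr_empty(), data.frame(localization = character(0)))
    }

    # variants: genotypes, tags, truth filter flags
    var_rows <- list()
    for (id in ids) {
      vs <- tr[[id]]$vars
      if (length(vs) == 0L) next
      o <- order(vapply(vs, `[[`, integer(1), "pos"))
      vs <- vs[o]
      pos <- vapply(vs, `[[`, integer(1), "pos")
      len <- nchar(tr[[id]]$seq)
      for (i in seq_along(vs)) {
        v <- vs[[i]]
        n_alts <- length(strsplit(v$alt, ",", fixed = TRUE)[[1]])
        pat <- draw_pattern(params$species, params$heterozygosity, n_alts)
        # generator-side filter truth (plain loops over planted positions)
        others <- pos[-i]
        t_cs <- length(others) > 0L && min(abs(others - v$pos)) < 60L
        t_cl <- min(v$pos, len - 1L - v$pos) < 60L
        t_hv <- FALSE
        if (length(pos) >= 6L) {
          for (j in seq_len(length(pos) - 5L)) {
            if (i >= j && i <= j + 5L && pos[j + 5L] - pos[j] <= 99L) {
              t_hv <- TRUE; break
            }
          }
        }
        t_cef <- sim_cef(tr[[id]]$seq, v$pos, v$ref,
                         strsplit(v$alt, ",", fixed = TRUE)[[1]], enzymes)
        var_rows[[length(var_rows) + 1L]] <- list(
          transcript_id = id, pos = v$pos, ref = v$ref, alt = v$alt,
          kind = v$kind, group = v$group, gt = pat$gt,
          intraspecific = pat$intra, interspecific = pat$inter,
          cs60 = t_cs, cl60 = t_cl, hv = t_hv, cef_pass = t_cef,
          filtered = !t_cs && !t_cl && !t_hv && t_cef)
      }
    }

    variants <- data.frame(
      transcript_id = vapply(var_rows, `[[`, character(1), "transcript_id"),
      pos = vapply(var_rows, `[[`, integer(1), "pos"),
      ref = vapply(var_rows, `[[`, character(1), "ref"),
      alt = vapply(var_rows, `[[`, character(1), "alt"),
      stringsAsFactors = FALSE)
    for (si in seq_len(nrow(panel))) {
      sp <- panel$species_id[si]
      variants[[panel$sample_id[si]]] <-
        vapply(var_rows, function(r) r$gt[[sp]], character(1))
    }
    attr(variants, "samples") <- panel$sample_id

    truth_variants <- data.frame(
      transcript_id = variants$transcript_id, pos = variants$pos,
      ref = variants$ref, alt = variants$alt,
      kind = vapply(var_rows, `[[`, character(1), "kind"),
      group = vapply(var_rows, `[[`, character(1), "group"),
      intraspecific = vapply(var_rows, `[[`, character(1), "intraspecific"),
      interspecific = vapply(var_rows, `[[`, character(1), "interspecific"),
      cs60 = vapply(var_rows, `[[`, logical(1), "cs60"),
      cl60 = vapply(var_rows, `[[`, logical(1), "cl60"),
      hv = vapply(var_rows, `[[`, logical(1), "hv"),
      cef_pass = vapply(var_rows, `[[`, logical(1), "cef_pass"),
      filtered = vapply(var_rows, `[[`, logical(1), "filtered"),
      stringsAsFactors = FALSE)

    out <- list(transcripts = seqs, orfs = orfs, variants = variants,
                panel = panel,
                truth = list(ssrs = truth_ssrs, variants = truth_variants),
                params = params)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(seqs, file.path(out_dir, "transcripts.fasta"))
      write_orf_bed(orfs, file.path(out_dir, "orfs.bed"))
      write_vcf(variants, file.path(out_dir, "variants.vcf"))
      write_species_panel(panel, file.path(out_dir, "panel.tsv"))
      write_marker_table(truth_ssrs, file.path(out_dir, "truth_ssrs.tsv"))
      write_marker_table(truth_variants,
                         file.path(out_dir, "truth_variants.tsv"))
    }
    out
  })
}
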