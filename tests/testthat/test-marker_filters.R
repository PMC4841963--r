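test_that("CS60: strict closer-than on first-REF-base distance", {
  expect_equal(flag_cs60(toy_variants(c(100, 150))), c(TRUE, TRUE))   # 50
  expect_equal(flag_cs60(toy_variants(c(100, 160))), c(FALSE, FALSE)) # exactly 60
  expect_equal(flag_cs60(toy_variants(100)), FALSE)                   # no neighbor
  # different transcripts never interact
  v <- rbind(toy_variants(100), toy_variants(130, tid = "t2"))
  attr(v, "samples") <- "S1"
  expect_equal(flag_cs60(v), c(FALSE, FALSE))
})

test_that("CL60: strict closer-than to either transcript edge", {
  lens <- c(t1 = 1000L)
  expect_true(flag_cl60(toy_variants(59), lens))
  expect_false(flag_cl60(toy_variants(60), lens))
  expect_true(flag_cl60(toy_variants(950), lens))   # 49 from right edge
  expect_false(flag_cl60(toy_variants(939), lens))  # exactly 60 from right
})

test_that("HV: strictly more than 5 variants in a sliding 100-nt window", {
  six <- toy_variants(c(0, 18, 36, 54, 72, 90))
  expect_equal(flag_hv(six), rep(TRUE, 6))
  five <- toy_variants(c(0, 22, 45, 67, 90))
  expect_equal(flag_hv(five), rep(FALSE, 5))
  # six variants spanning exactly 100 nt: no window holds all six
  wide <- toy_variants(c(0, 20, 40, 60, 80, 100))
  expect_equal(flag_hv(wide), rep(FALSE, 6))
})

test_that("CS/CL/HV equal exhaustive scans on random fixtures", {
  set.seed(88)
  for (rep in 1:120) {
    n <- sample(2:40, 1)
    len <- 2000L
    pos <- sort(sample(0:(len - 1), n))
    v <- toy_variants(pos)
    expect_equal(flag_cs60(v), oracle_cs(pos), info = rep)
    expect_equal(unname(flag_cl60(v, c(t1 = len))), oracle_cl(pos, len),
                 info = rep)
    expect_equal(flag_hv(v), oracle_hv(pos), info = rep)
  }
})

test_that("CEF: planted EcoRI site is differential, absence is not", {
  enz <- read_enzymes()
  set.seed(5)
  base <- rand_seq(400)
  # remove any catalogue site already present, then plant GAATTC at 200
  seq <- gsub("GAATTC", "GTATTC", base, fixed = TRUE)
  substr(seq, 201, 206) <- "GAATTC"
  # variant at site offset 2 (0-based pos 202): A -> C destroys the site
  v <- toy_variants(202, ref = "A", alt = "C")
  res <- flag_cef(v, c(t1 = seq), enz)
  expect_true(res$cef_pass)
  expect_true(grepl("EcoRI", res$cef_enzymes))

  # no recognition site anywhere near the variant -> not differential
  clean <- strrep("ACAC", 100)  # repeat devoid of any catalogue site
  v2 <- toy_variants(200, ref = "A", alt = "T")
  res2 <- flag_cef(v2, c(t1 = clean), enz)
  # A->T inside (AC)n creates no 6-cutter site from this catalogue except
  # none: verify against the digestion oracle rather than assuming
  expect_equal(res2$cef_pass,
               oracle_cef(clean, 200L, "A", "T", enz))
})

test_that("CEF handles degenerate IUPAC sites on both strands", {
  enzW <- data.frame(name = "TestW", site = "GGWCC", common = TRUE)
  pad <- strrep("ATTA", 30)
  seq <- pad
  substr(seq, 61, 65) <- "GGACC"      # W matches A
  v <- toy_variants(62, ref = "A", alt = "C")  # GGACC -> GGCCC: destroyed
  expect_true(flag_cef(v, c(t1 = seq), enzW)$cef_pass)
  # W also matches T
  substr(seq, 61, 65) <- "GGTCC"
  v <- toy_variants(62, ref = "T", alt = "G")
  expect_true(flag_cef(v, c(t1 = seq), enzW)$cef_pass)
  # palindrome-on-minus-strand: plant revcomp of a non-palindromic site
  enzA <- data.frame(name = "TestA", site = "GACGTG", common = TRUE)
  seq2 <- pad
  substr(seq2, 61, 66) <- "CACGTC"    # revcomp(GACGTG)
  v <- toy_variants(61, ref = "A", alt = "T")
  expect_true(flag_cef(v, c(t1 = seq2), enzA)$cef_pass)
})

test_that("CEF equals full digestion simulation on random fixtures", {
  enz <- read_enzymes()
  set.seed(19)
  for (rep in 1:100) {
    seq <- rand_seq(2000)
    pos <- sample(100:1900, 3)
    for (p in pos) {
      ref <- substr(seq, p + 1, p + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      # half the time plant a site over the variant to enrich positives
      if (rep %% 2 == 0) {
        e <- enz[sample.int(nrow(enz), 1), ]
        o <- sample(seq_len(nchar(e$site)), 1) - 1
        inst <- vapply(strsplit(e$site, "")[[1]], function(ch)
          sample(oracle_iupac[[ch]], 1), character(1))
        substr(seq, p - o + 1, p - o + nchar(e$site)) <-
          paste(inst, collapse = "")
        ref <- substr(seq, p + 1, p + 1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      }
      v <- toy_variants(p, ref = ref, alt = alt)
      got <- flag_cef(v, c(t1 = seq), enz)$cef_pass
      expect_equal(got, oracle_cef(seq, p, ref, alt, enz),
                   info = paste(rep, p))
    }
  }
})

test_that("multi-allelic CEF passes if any ALT is differential", {
  enz <- read_enzymes()
  seq <- strrep("ATTA", 100)
  substr(seq, 201, 206) <- "GAATTC"
  # alt1 A->G keeps no site either way? alt2 destroys; site offset 3 (T)
  v <- toy_variants(203, ref = "T", alt = "T,G")  # first "alt" == ref is inert
  v$alt <- "TT,G"  # indel alt plus SNP alt; the G destroys the site
  res <- flag_cef(v, c(t1 = seq), enz)
  expect_true(res$cef_pass)
})

test_that("cascade conjunction, monotonicity and order invariance", {
  set.seed(23)
  seq <- rand_seq(1500)
  pos <- c(30L, 200L, 270L, 700L, 705L, 710L, 715L, 720L, 725L, 1200L)
  v <- toy_variants(pos)
  v$ref <- vapply(pos, function(p) substr(seq, p + 1, p + 1), character(1))
  v$alt <- vapply(v$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  enz <- read_enzymes()
  flagged <- apply_filters(v, c(t1 = seq), enz)
  expect_equal(flagged$filtered,
               !flagged$cs60 & !flagged$cl60 & !flagged$hv & flagged$cef_pass)
  expect_true(flagged$cl60[1])                       # pos 30
  expect_true(all(flagged$hv[4:9]))                  # 6 within 25 nt
  expect_false(any(flagged$cs60[c(2, 3, 10)]))       # 70+ nt spacing passes

  # shrinking the catalogue never flips cef FALSE -> TRUE
  sub <- enz[1:5, ]
  f2 <- apply_filters(v, c(t1 = seq), sub)
  expect_true(all(!f2$cef_pass | flagged$cef_pass))
  # growing CS/CL thresholds never unflags
  f3 <- apply_filters(v, c(t1 = seq), enz, cs = 80L, cl = 80L)
  expect_true(all(flagged$cs60 <= f3$cs60))
  expect_true(all(flagged$cl60 <= f3$cl60))

  # input order invariance
  perm <- sample(nrow(v))
  vp <- v[perm, ]; attr(vp, "samples") <- attr(v, "samples")
  fp <- apply_filters(vp, c(t1 = seq), enz)
  expect_equal(fp$filtered[order(perm)], flagged$filtered)
})
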