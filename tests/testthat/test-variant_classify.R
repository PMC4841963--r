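test_that("kind split: SNP iff all alleles are single bases", {
  v <- toy_variants(c(1, 2, 3, 4), ref = "A", alt = "G")
  v$ref <- c("A", "A", "ACT", "A")
  v$alt <- c("G", "AT", "A", "G,T")
  expect_equal(classify_kind(v), c("SNP", "INDEL", "INDEL", "SNP"))
  v$alt <- c("G", "AT", "A", "G,TT")
  expect_equal(classify_kind(v)[4], "INDEL")
})

test_that("intraspecific = heterozygous; interspecific = hom-differential", {
  panel <- toy_panel()
  # het in INC only: intraspecific INC, no interspecific combos
  v <- panel_variants(list(AET = "0/0", INC = "0/1", MEL = "0/0",
                           TOR = "0/0"))
  t <- classify_species(v, panel)
  expect_equal(t$intraspecific, "INC")
  expect_equal(t$interspecific, "")

  # classic pair: INC 0/0, AET 1/1 (others missing)
  v <- panel_variants(list(AET = "1/1", INC = "0/0", MEL = "./.",
                           TOR = "./."))
  t <- classify_species(v, panel)
  expect_equal(t$intraspecific, "")
  expect_equal(t$interspecific, "AET+INC")

  # a site het in INC can still be interspecific for {MEL,TOR}
  v <- panel_variants(list(AET = "./.", INC = "0/1", MEL = "0/0",
                           TOR = "1/1"))
  t <- classify_species(v, panel)
  expect_equal(t$intraspecific, "INC")
  expect_equal(t$interspecific, "MEL+TOR")

  # multi-allelic: allele identity matters, not just 0/1
  v <- panel_variants(list(AET = "1/1", INC = "2/2", MEL = "./.",
                           TOR = "./."), alt = "G,T")
  expect_equal(classify_species(v, panel)$interspecific, "AET+INC")
  v <- panel_variants(list(AET = "1/1", INC = "1/1", MEL = "./.",
                           TOR = "./."), alt = "G,T")
  expect_equal(classify_species(v, panel)$interspecific, "")
})

test_that("all 2/3/4-way combinations match brute-force enumeration", {
  panel <- toy_panel()
  species <- panel$species_id
  gts <- c("0/0", "1/1", "0/1", "./.")
  set.seed(9)
  cases <- c(
    list(c("0/0", "0/0", "1/1", "1/1")),   # worked example: all combos mixing 0/1 carriers
    lapply(1:120, function(i) sample(gts, 4, replace = TRUE)))
  for (gt in cases) {
    names(gt) <- species
    v <- panel_variants(as.list(gt))
    got <- classify_species(v, panel)$interspecific
    # independent enumeration
    hom <- vapply(gt, function(g) g %in% c("0/0", "1/1"), logical(1))
    al <- substr(gt, 1, 1)
    combos <- character(0)
    for (k in 2:4) {
      cmb <- utils::combn(species, k, simplify = FALSE)
      for (sub in cmb) {
        if (all(hom[sub]) && length(unique(al[sub])) >= 2) {
          combos <- c(combos, paste(sub, collapse = "+"))
        }
      }
    }
    expect_equal(got, paste(combos, collapse = ";"),
                 info = paste(gt, collapse = " "))
  }
  # the worked example includes the 4-way tag
  v <- panel_variants(list(AET = "0/0", INC = "0/0", MEL = "1/1",
                           TOR = "1/1"))
  expect_true(grepl("AET\\+INC\\+MEL\\+TOR",
                    classify_species(v, panel)$interspecific))
})

test_that("tags are symmetric in species order and monotone under masking", {
  p1 <- toy_panel(c("AET", "INC"))
  p2 <- p1[2:1, ]
  v <- panel_variants(list(AET = "1/1", INC = "0/0"))
  expect_equal(classify_species(v, p1)$interspecific,
               classify_species(v, p2)$interspecific)

  set.seed(31)
  panel <- toy_panel()
  for (i in 1:40) {
    gt <- sample(c("0/0", "1/1", "0/1"), 4, replace = TRUE)
    names(gt) <- panel$species_id
    v <- panel_variants(as.list(gt))
    full <- classify_species(v, panel)
    mask <- gt; mask[[sample(names(gt), 1)]] <- "./."
    vm <- panel_variants(as.list(mask))
    masked <- classify_species(vm, panel)
    tags <- function(t) unlist(strsplit(c(
      strsplit(t$intraspecific, ",")[[1]],
      strsplit(t$interspecific, ";")[[1]]), ";"))
    expect_true(all(tags(masked) %in% tags(full)))
  }
})

test_that("multi-sample species need unanimity for hom, any-het for het", {
  panel <- data.frame(sample_id = c("A1", "A2", "B1"),
                      species_id = c("AET", "AET", "INC"))
  v <- panel_variants(list(A1 = "0/0", A2 = "0/0", B1 = "1/1"))
  t <- classify_species(v, panel)
  expect_equal(t$interspecific, "AET+INC")

  v <- panel_variants(list(A1 = "0/0", A2 = "0/1", B1 = "1/1"))
  t <- classify_species(v, panel)
  expect_equal(t$intraspecific, "AET")
  expect_equal(t$interspecific, "")

  # discordant homs: neither het nor hom-for-one-allele
  v <- panel_variants(list(A1 = "0/0", A2 = "1/1", B1 = "1/1"))
  t <- classify_species(v, panel)
  expect_equal(t$intraspecific, "")
  expect_equal(t$interspecific, "")
})

test_that("count_by_category partitions kinds and respects tags", {
  panel <- toy_panel()
  set.seed(77)
  rows <- lapply(1:60, function(i) {
    gt <- sample(c("0/0", "1/1", "0/1", "./."), 4, replace = TRUE)
    names(gt) <- panel$species_id
    panel_variants(as.list(gt), pos = 100L + 70L * i,
                   ref = "A", alt = if (i %% 5 == 0) "AT" else "G")
  })
  v <- do.call(rbind, rows)
  attr(v, "samples") <- panel$sample_id
  tagged <- classify_species(v, panel)
  tab <- count_by_category(tagged, panel)
  expect_equal(tab$total, tab$snps + tab$indels)     # kind partition
  expect_true(all(tab$filtered %in% NA_integer_))    # no flags yet
  # per-category totals equal direct tag counts
  aet <- sum(grepl("(^|,)AET($|,)", tagged$intraspecific))
  expect_equal(tab$total[tab$category == "AET" &
                           tab$type == "intraspecific"], aet)
  pair <- sum(grepl("(^|;)AET\\+INC($|;)", tagged$interspecific))
  expect_equal(tab$total[tab$category == "AET+INC"], pair)
  # empty input -> all-zero table
  empty <- count_by_category(tagged[0, ], panel)
  expect_true(all(empty$total == 0L))
  expect_equal(nrow(empty), 4 + 6 + 4 + 1)
})
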