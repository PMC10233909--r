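test_that("quality tiers follow the fixed MIMAG-style evaluation order", {
  q <- data.frame(
    genome_id = paste0("g", 1:6),
    completeness = c(95, 95, 95, 60, 40, 90),
    contamination = c(2, 2, 2, 8, 3, 2),
    n_trna = c(20, 20, 10, 0, 0, 20),
    rrna_operon_complete = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  tiers <- as.character(assignQualityTier(q)$tier)
  expect_equal(tiers[1], "high")
  expect_equal(tiers[2], "nearly_complete")  # rRNA operon missing
  expect_equal(tiers[3], "nearly_complete")  # too few tRNAs
  expect_equal(tiers[4], "medium")
  expect_equal(tiers[5], "reject")
  # completeness exactly 90 with full extras is high, but not nearly
  # complete (that tier needs > 90)
  expect_equal(tiers[6], "high")
  q6 <- q[6, ]; q6$rrna_operon_complete <- FALSE
  expect_equal(as.character(assignQualityTier(q6)$tier), "medium")
  expect_error(assignQualityTier(transform(q, completeness = 150)), "100")
})

test_that("tiers are monotone in completeness and anti-monotone in contamination", {
  rank_of <- c(reject = 0, medium = 1, nearly_complete = 2, high = 3)
  grid <- expand.grid(comp = c(30, 50, 70, 90, 91, 100),
                      cont = c(0, 4.9, 5, 9.9, 10, 20))
  q <- data.frame(genome_id = seq_len(nrow(grid)),
                  completeness = grid$comp, contamination = grid$cont,
                  n_trna = 20, rrna_operon_complete = TRUE)
  r <- rank_of[as.character(assignQualityTier(q)$tier)]
  for (cont in unique(grid$cont)) {
    i <- order(grid$comp)[grid$cont[order(grid$comp)] == cont]
    expect_true(all(diff(r[i]) >= 0))
  }
  for (comp in unique(grid$comp)) {
    i <- order(grid$cont)[grid$comp[order(grid$cont)] == comp]
    expect_true(all(diff(r[i]) <= 0))
  }
})

test_that("species edges need both the ANI and alignment-fraction thresholds", {
  mk <- function(ani, af) {
    a <- matrix(c(100, ani, ani, 100), 2,
                dimnames = list(c("g1", "g2"), c("g1", "g2")))
    f <- matrix(c(1, af, af, 1), 2, dimnames = dimnames(a))
    ANIMatrix(a, f)
  }
  qual <- data.frame(genome_id = c("g1", "g2"),
                     completeness = c(95, 80), contamination = c(1, 2))
  expect_equal(max(dereplicateGenomes(mk(96, 0.8), qual)$clusters$cluster), 1L)
  expect_equal(max(dereplicateGenomes(mk(96, 0.5), qual)$clusters$cluster), 2L)
  expect_equal(max(dereplicateGenomes(mk(94, 0.8), qual)$clusters$cluster), 2L)
  expect_error(dereplicateGenomes(mk(96, 0.8), qual[1, ]), "quality")
})

test_that("dereplication recovers planted species and matches union-find", {
  cfg <- phycoConfig()
  for (seed in 1:10) {
    sim <- simANIMatrix(n_species = 4L, genomes_per_species = 3L, seed = seed)
    qual <- data.frame(genome_id = genomeIds(sim$ani),
                       completeness = runif(12, 60, 100),
                       contamination = runif(12, 0, 4))
    res <- dereplicateGenomes(sim$ani, qual, cfg)
    # planted species recovered exactly
    tab <- table(res$clusters$cluster,
                 sim$truth$species[match(res$clusters$genome_id,
                                         sim$truth$genome_id)])
    expect_equal(max(res$clusters$cluster), 4L)
    expect_true(all(rowSums(tab > 0) == 1L))
    # component structure equals the union-find oracle
    adj <- aniValues(sim$ani) >= cfg@aniSpecies &
      alignFractions(sim$ani) >= cfg@aniAlignmentMin
    diag(adj) <- FALSE
    oc <- oracleComponents(adj)
    expect_equal(length(unique(oc)), max(res$clusters$cluster))
    expect_true(all(tapply(oc, res$clusters$cluster,
                           function(x) length(unique(x))) == 1L))
    # representative maximizes completeness - 5 * contamination
    score <- setNames(qual$completeness - 5 * qual$contamination,
                      qual$genome_id)
    for (k in seq_len(max(res$clusters$cluster))) {
      members <- res$clusters$genome_id[res$clusters$cluster == k]
      expect_equal(unname(score[res$representatives[k]]),
                   max(score[members]))
    }
    # representatives within non-redundant set within input; no two
    # retained genomes within a cluster at >= 99 ANI
    expect_true(all(res$representatives %in% res$nonredundant))
    a <- aniValues(sim$ani)
    for (k in seq_len(max(res$clusters$cluster))) {
      kept <- intersect(res$nonredundant,
                        res$clusters$genome_id[res$clusters$cluster == k])
      if (length(kept) > 1L) {
        off <- a[kept, kept][upper.tri(diag(length(kept)))]
        expect_true(all(off < cfg@aniRedundancy))
      }
    }
  }
  # single genome trivially forms one cluster
  one <- ANIMatrix(matrix(100, 1, 1, dimnames = list("g1", "g1")))
  res1 <- dereplicateGenomes(one, data.frame(genome_id = "g1",
                                             completeness = 90,
                                             contamination = 1))
  expect_equal(res1$clusters$cluster, 1L)
  expect_equal(res1$representatives, "g1")
})

test_that("taxonomy reconciliation follows the agreement truth table", {
  mk <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r) {
      lin <- c(r$lineage, rep("", 7 - length(r$lineage)))
      data.frame(genome_id = "g1", source = r$source,
                 domain = lin[1], phylum = lin[2], class = lin[3],
                 order = lin[4], family = lin[5], genus = lin[6],
                 species = lin[7], stringsAsFactors = FALSE)
    }))
  }
  base <- c("Bacteria", "Bacteroidota", "Bacteroidia", "Flavobacteriales",
            "Flavobacteriaceae", "Maribacter", "sp1")

  # full agreement: lineage accepted, no conflicts
  r <- reconcileTaxonomy(mk(list(source = "GTDB", lineage = base),
                            list(source = "SILVA", lineage = base)))
  expect_equal(unname(unlist(r$consensus[1, -1])), base)
  expect_equal(nrow(r$conflicts), 0L)

  # 2-of-3 majority at genus
  alt <- base; alt[6] <- "Zobellia"
  r <- reconcileTaxonomy(mk(list(source = "GTDB", lineage = alt),
                            list(source = "SILVA", lineage = base),
                            list(source = "EZTAXON", lineage = base)))
  expect_equal(r$consensus$genus, "Maribacter")  # SILVA + EZTAXON outvote
  expect_equal(r$conflicts$resolved, "majority")

  # two-source conflict at family: GTDB preferred by default...
  altf <- base; altf[5] <- "Schleiferiaceae"
  r <- reconcileTaxonomy(mk(list(source = "GTDB", lineage = altf),
                            list(source = "SILVA", lineage = base)))
  expect_equal(r$consensus$family, "Schleiferiaceae")
  expect_equal(r$conflicts$resolved, "prefer_GTDB")
  # ... or the lineage truncates after order with prefer = "none"
  r <- reconcileTaxonomy(mk(list(source = "GTDB", lineage = altf),
                            list(source = "SILVA", lineage = base)),
                         prefer = "none")
  expect_equal(r$consensus$order, "Flavobacteriales")
  expect_true(is.na(r$consensus$family))
  expect_true(is.na(r$consensus$genus))
  expect_equal(r$conflicts$resolved, "unresolved")

  # sources stopping early: consensus uses whoever still reports a rank
  short <- base[1:4]
  r <- reconcileTaxonomy(mk(list(source = "GTDB", lineage = short),
                            list(source = "SILVA", lineage = base)))
  expect_equal(r$consensus$genus, "Maribacter")
})

test_that("reconciled lineages are always rank prefixes", {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  set.seed(19)
  vals <- c("x", "y")
  for (i in 1:30) {
    nsrc <- sample(2:3, 1)
    src <- c("GTDB", "SILVA", "EZTAXON")[1:nsrc]
    rows <- do.call(rbind, lapply(src, function(s) {
      lin <- sample(vals, 7, replace = TRUE)
      stopat <- sample(3:7, 1)
      lin[seq_len(7) > stopat] <- ""
      out <- data.frame(genome_id = "g", source = s, stringsAsFactors = FALSE)
      for (k in seq_along(ranks)) out[[ranks[k]]] <- lin[k]
      out
    }))
    cons <- reconcileTaxonomy(rows)$consensus
    filled <- !is.na(unlist(cons[1, ranks])) & nzchar(unlist(cons[1, ranks]))
    if (any(!filled)) {
      expect_true(all(which(!filled) > max(0, which(filled))))
    }
  }
})

test_that("BGC summaries recount classes and contig-edge fractions", {
  rec <- data.frame(genome_id = "g", contig_id = "c",
                    bgc_class = c("terpene", "terpene", "terpene", "NRPS"),
                    on_contig_edge = c(TRUE, FALSE, FALSE, FALSE),
                    source = c("DG", "DG", "MAG", "MAG"))
  s <- summarizeBGCs(rec)
  expect_equal(s$edge_fraction, 0.25)
  expect_equal(s$classes$percent[s$classes$bgc_class == "terpene"], 75)
  expect_equal(s$classes$percent[s$classes$bgc_class == "NRPS"], 25)
  expect_equal(sum(s$classes$percent), 100)
  expect_equal(s$edge_by_source$edge_fraction[s$edge_by_source$source == "DG"],
               0.5)
  # naive recount on random records
  set.seed(3)
  rec <- data.frame(genome_id = "g", contig_id = "c",
                    bgc_class = sample(c("terpene", "bacteriocin", "NRPS",
                                         "T1PKS"), 200, replace = TRUE),
                    on_contig_edge = runif(200) < 0.3)
  s <- summarizeBGCs(rec)
  expect_equal(s$edge_fraction, mean(rec$on_contig_edge))
  for (k in seq_len(nrow(s$classes))) {
    expect_equal(s$classes$n[k], sum(rec$bgc_class == s$classes$bgc_class[k]))
  }
  empty <- summarizeBGCs(rec[0, ])
  expect_equal(nrow(empty$classes), 0L)
})
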