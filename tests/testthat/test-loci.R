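mkAnn <- function(roles_fams, genome_id = "g") {
  # roles_fams: character vector; "susC"/"susD"/"tonB"/"sulfatase" are
  # roles, "-" a plain gene, anything else a CAZyme family label
  n <- length(roles_fams)
  is_role <- roles_fams %in% c("susC", "susD", "tonB", "sulfatase")
  GenomeAnnotation(genome_id, data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), contig_id = "c1",
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    cazy_families = ifelse(is_role | roles_fams == "-", "", roles_fams),
    role = ifelse(is_role, roles_fams, "none"),
    stringsAsFactors = FALSE))
}

test_that("markers chain within the sliding window and split at it", {
  ls <- detectLoci(mkAnn(c("susC", "susD", "GH16", "GH3")))
  expect_equal(length(ls), 1L)
  l <- loci(ls)
  expect_equal(c(l$first_index, l$last_index), c(0L, 3L))
  expect_equal(l$category, "PUL")

  # gap of exactly windowGenes (10) splits; gap of 9 chains
  split10 <- detectLoci(mkAnn(c("GH16", rep("-", 10), "GH3", "CE1", "CE2")))
  expect_equal(nrow(allCandidateSpans(split10)), 2L)
  chain9 <- detectLoci(mkAnn(c("GH16", rep("-", 9), "GH3", "CE1", "CE2")))
  expect_equal(nrow(allCandidateSpans(chain9)), 1L)
})

test_that("detection equals the all-pairs chaining oracle on random genomes", {
  cfg <- phycoConfig()
  for (seed in 1:40) {
    ann <- randomAnnotation(sample(50:300, 1), seed = seed)
    ls <- detectLoci(ann, cfg)
    spans <- allCandidateSpans(ls)
    groups <- oracleChainMarkers(markerPositions(ann, cfg), cfg@windowGenes)
    expect_equal(nrow(spans), length(groups))
    expect_equal(spans$first, vapply(groups, min, integer(1)))
    expect_equal(spans$last, vapply(groups, max, integer(1)))
  }
})

test_that("loci partition the chained markers without overlap", {
  for (seed in 1:10) {
    ann <- randomAnnotation(200, seed = 1000 + seed)
    ls <- detectLoci(ann)
    spans <- allCandidateSpans(ls)
    if (nrow(spans) > 1L) {
      expect_true(all(spans$first[-1] > spans$last[-nrow(spans)]))
    }
    covered <- unlist(Map(seq, spans$first, spans$last))
    expect_true(all(markerPositions(ann) %in% covered))
  }
})

test_that("composition rules place loci in the four categories", {
  cat1 <- function(x) loci(detectLoci(mkAnn(x)))$category
  expect_equal(cat1(c("GH16", "susC", "susD")), "PUL")
  expect_equal(cat1(c("GH16", "tonB")), "PUL_like")
  expect_equal(cat1(c("GH16", "susC")), "PUL_like")
  expect_equal(cat1(c("GH3", "GH16", "CE1")), "CGC")
  expect_equal(cat1(c("susC", "susD")), "susCD_only")
  # non-categorizable candidates are dropped with a record
  ls <- detectLoci(mkAnn(c("sulfatase")))
  expect_equal(length(ls), 0L)
  expect_equal(nrow(droppedLoci(ls)), 1L)
  ls2 <- detectLoci(mkAnn(c("GH16", "GH3")))  # below cgcMinCazymes
  expect_equal(length(ls2), 0L)
  expect_equal(nrow(droppedLoci(ls2)), 1L)
  # GT-only genes neither seed nor count
  expect_equal(length(detectLoci(mkAnn(c("GT2", "GT4", "GT2")))), 0L)
})

test_that("susCD architectures are typed from pair adjacency", {
  expect_equal(typeArchitecture(c("susC", "susD", "none")), "single")
  expect_equal(typeArchitecture(c("susC", "susD", "susC", "susD")),
               "tandem_repeat")
  expect_equal(typeArchitecture(c("susC", "susD", "none", "susC")), "hybrid")
  expect_equal(typeArchitecture(c("susC", "susD", "susC", "susD", "susC")),
               "tandem_repeat_hybrid")
  expect_equal(typeArchitecture(c("susC", "none", "susD")), "none")
  # well-separated pairs with nothing unpaired fit no named architecture
  expect_equal(typeArchitecture(c("susC", "susD", "none", "none",
                                  "susC", "susD")), "none")
  # susD-susC adjacency pairs only under the relaxed orientation
  expect_equal(typeArchitecture(c("susD", "susC")), "none")
  expect_equal(typeArchitecture(c("susD", "susC"), orientation = "both"),
               "single")
})

test_that("locus statistics recount composition exactly", {
  gs <- simAnnotatedGenome(
    n_contigs = 3L, genes_per_contig = 200L,
    planted_loci = list(
      list(category = "PUL", architecture = "single",
           cazy_families = c("GH16", "GH3"), n_sulfatases = 1L),
      list(category = "PUL", architecture = "single",
           cazy_families = c("PL7", "PL6", "PL17")),
      list(category = "CGC", architecture = "none",
           cazy_families = c("CE1", "CE3", "CE1"))),
    background_cazyme_rate = 0, seed = 2)
  ls <- detectLoci(gs$annotation)
  st <- locusStatistics(ls, setNames(list(gs$annotation), genomeId(gs$annotation)))
  cats <- st$categories
  expect_equal(cats$n[cats$category == "PUL"], 2L)
  expect_equal(cats$sulfatase_fraction[cats$category == "PUL"], 0.5)
  l <- loci(ls)
  expect_equal(cats$mean_length[cats$category == "PUL"],
               mean(l$n_genes[l$category == "PUL"]))
  expect_equal(cats$mean_cazyme_density[cats$category == "PUL"],
               mean(l$cazyme_density[l$category == "PUL"]))
  # all CAZymes sit inside PULs or the CGC; PUL share is 5 of 8
  g <- st$genomes
  expect_equal(g$n_pul, 2L)
  expect_equal(g$pct_cazymes_in_pul, 100 * 5 / 8)
})

test_that("a 99-gene tandem-repeat-hybrid PUL reports its size and density", {
  # replica of the largest-PUL shape: 99 genes, 48 CAZymes
  fams <- rep(c("GH29", "GH106", "PL25", "PL40"), length.out = 48)
  body <- character(0)
  for (i in 1:48) {  # 48 CAZymes with 46 single-gene spacers
    body <- c(body, fams[i])
    if (i <= 46) body <- c(body, "-")
  }
  ann <- mkAnn(c("susC", "susD", "susC", "susD", "susC", body))
  ls <- detectLoci(ann)
  l <- loci(ls)
  expect_equal(l$n_genes, 99L)
  expect_equal(l$n_cazymes, 48L)
  expect_equal(l$category, "PUL")
  expect_equal(l$architecture, "tandem_repeat_hybrid")
  expect_equal(l$cazyme_density, 48 / 99, tolerance = 1e-12)
})

test_that("widening the window can only merge candidate loci", {
  for (seed in 1:10) {
    ann <- randomAnnotation(250, seed = 2000 + seed)
    counts <- vapply(c(2L, 5L, 10L, 15L, 25L), function(w)
      nrow(allCandidateSpans(detectLoci(ann, phycoConfig(windowGenes = w)))),
      integer(1))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("signal-peptide fractions recount per CAZyme class", {
  n <- 8L
  ann <- GenomeAnnotation("g", data.frame(
    gene_id = sprintf("g%d", 1:n), contig_id = "c1",
    start = (1:n - 1L) * 1000L + 1L, end = (1:n - 1L) * 1000L + 900L,
    cazy_families = c("PL7", "PL6", "PL12", "PL17", "GH16;CBM6", "GH3",
                      "GT2", ""),
    signal_peptide = c(1, 1, 1, 0, 1, 0, 0, 1),
    stringsAsFactors = FALSE))
  s <- secretionSummary(ann)
  expect_equal(s$fraction[s$class == "PL"], 0.75)
  expect_equal(s$n_genes[s$class == "GH"], 2L)
  expect_equal(s$fraction[s$class == "GH"], 0.5)
  # the mixed GH16;CBM6 gene counts once in each class
  expect_equal(s$n_genes[s$class == "CBM"], 1L)
  expect_equal(s$fraction[s$class == "CBM"], 1)
  expect_equal(nrow(secretionSummary(mkAnn(c("-", "susC")))), 0L)
})
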