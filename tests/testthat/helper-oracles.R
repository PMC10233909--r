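# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the slowest, most literal formulation of each rule.

# all-pairs gap check + transitive closure over sorted marker positions;
# returns a list of marker-position groups (chained loci)
oracleChainMarkers <- function(marker_pos, window) {
  m <- sort(marker_pos)
  n <- length(m)
  if (n == 0L) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- abs(m[i] - m[j]) - 1L < window
    }
  }
  # transitive closure by repeated squaring
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[which(adj[i, ])] <- k
    }
  }
  lapply(seq_len(k), function(g) m[comp == g])
}

# literal double loop over taxa x habitats
oracleQualify <- function(values, habitat, cfg) {
  out <- NULL
  for (tx in rownames(values)) {
    for (h in unique(habitat)) {
      vh <- values[tx, habitat == h]
      prev <- sum(vh > cfg@presenceFloor) / length(vh)
      q <- prev >= cfg@prevalenceMin && max(vh) >= cfg@abundanceMin
      out <- rbind(out, data.frame(taxon = tx, habitat = h,
                                   qualifies = q,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# exponential LCS: enumerate every subsequence of a, keep the longest that
# is also a subsequence of b
oracleLCS <- function(a, b) {
  isSubseq <- function(s, x) {
    if (!length(s)) return(TRUE)
    j <- 1L
    for (v in x) {
      if (v == s[j]) {
        j <- j + 1L
        if (j > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  for (mask in 0:(2^length(a) - 1L)) {
    s <- a[bitwAnd(mask, 2^(seq_along(a) - 1L)) > 0]
    if (length(s) > best && isSubseq(s, b)) best <- length(s)
  }
  best
}

# Monte-Carlo rarefaction: mean observed richness over B random subsamples
oracleRarefy <- function(counts, depth, B = 1e5) {
  pool <- rep(seq_along(counts), counts)
  obs <- vapply(seq_len(B), function(i)
    length(unique(pool[sample.int(length(pool), depth)])), integer(1))
  c(mean = mean(obs), se = stats::sd(obs) / sqrt(B))
}

# union-find over species edges for dereplication components
oracleComponents <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# random gene table for detection fuzzing: sprinkles roles and families
randomAnnotation <- function(n_genes, genome_id = "fuzz",
                             p_marker = 0.12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roles <- sample(c("none", "susC", "susD", "tonB", "sulfatase"),
                  n_genes, replace = TRUE,
                  prob = c(1 - p_marker, rep(p_marker / 4, 4)))
  fams <- ifelse(roles == "none" & runif(n_genes) < p_marker,
                 sample(c("GH16", "GH3", "PL7", "CE1", "CBM6", "AA3",
                          "GH13", "GT2"), n_genes, replace = TRUE), "")
  GenomeAnnotation(genome_id, data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    contig_id = "c1",
    start = (seq_len(n_genes) - 1L) * 1000L + 1L,
    end = (seq_len(n_genes) - 1L) * 1000L + 900L,
    cazy_families = fams, role = roles,
    stringsAsFactors = FALSE))
}

# marker positions (0-based gene_index) of an annotation under a config
markerPositions <- function(ann, cfg = phycoConfig()) {
  g <- genes(ann)
  caz <- vapply(as.list(g$cazy_families), function(f)
    any(sub("^(GH|GT|PL|CE|AA|CBM).*$", "\\1", f) %in% cfg@markerClasses),
    logical(1))
  g$gene_index[caz | g$role %in% c("susC", "susD", "tonB", "sulfatase")]
}

# all chained candidate spans (kept loci plus dropped candidates)
allCandidateSpans <- function(ls) {
  l <- loci(ls)
  d <- droppedLoci(ls)
  spans <- rbind(
    data.frame(first = l$first_index, last = l$last_index),
    data.frame(first = d$first_index, last = d$last_index))
  spans[order(spans$first), , drop = FALSE]
}

table1Fixture <- function() {
  readAbundanceTable(
    system.file("extdata", "table1_core_dominant_genera.tsv",
                package = "phycoPUL"),
    system.file("extdata", "table1_habitat_meta.tsv", package = "phycoPUL"),
    flag_col = "category")
}
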