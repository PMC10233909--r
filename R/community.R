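#' Qualify taxa per habitat by prevalence and abundance
#'
#' A taxon qualifies in a habitat when it is present (abundance strictly
#' above `presenceFloor`, default 0) in at least `prevalenceMin` of that
#' habitat's samples AND reaches `abundanceMin` percent in at least one
#' sample. With `abundanceScope = "habitat"` (default) the abundance
#' condition is evaluated within the habitat; with `"global"` a single
#' qualifying sample anywhere suffices wherever the taxon is prevalent.
#'
#' @param table an [AbundanceTable-class].
#' @param cfg a [PhycoConfig-class].
#' @param habitats optional habitat codes to evaluate; habitats requested
#'   but absent from the table are omitted with a warning. Default: all
#'   habitats present.
#'
#' @return A data.frame with one row per (taxon, habitat): `taxon`,
#'   `habitat`, `prevalence` (fraction of samples present), `max_abundance`
#'   (percent) and `qualifies`. Omitted habitats are recorded in
#'   `attr(, "omitted_habitats")`.
#' @export
qualifyTaxa <- function(table, cfg = phycoConfig(), habitats = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  v <- abundances(table)
  hab <- as.character(colData(table)$habitat)
  present <- unique(hab)
  if (is.null(habitats)) habitats <- intersect(.HABITATS, present)
  omitted <- setdiff(habitats, present)
  if (length(omitted)) {
    warning("habitat(s) with zero samples omitted: ",
            paste(omitted, collapse = ", "))
    habitats <- intersect(habitats, present)
  }
  global_hit <- apply(v, 1L, max) >= cfg@abundanceMin
  res <- do.call(rbind, lapply(habitats, function(h) {
    vh <- v[, hab == h, drop = FALSE]
    prev <- rowMeans(vh > cfg@presenceFloor)
    mx <- apply(vh, 1L, max)
    hit <- if (cfg@abundanceScope == "habitat") mx >= cfg@abundanceMin
           else global_hit
    data.frame(taxon = rownames(v), habitat = h, prevalence = prev,
               max_abundance = mx,
               qualifies = prev >= cfg@prevalenceMin & hit,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(res, "omitted_habitats") <- omitted
  res
}

#' Classify taxa into core / dominant / host-specific / background
#'
#' Categories are determined solely by the number of macroalgal habitats
#' (H, R, L, B) in which a taxon qualifies: 4 = core, 3 = dominant,
#' 1-2 = host-specific, 0 = background. Qualification in the seawater (S)
#' and sediment (N) controls is reported separately, never entering the
#' macroalgal category.
#'
#' @param qualifies output of [qualifyTaxa()].
#' @param cfg a [PhycoConfig-class] (reserved; categories depend only on
#'   the qualification pattern).
#' @return A data.frame with `taxon`, `n_macroalgal`, `category` and, when
#'   controls are present, logical `qualifies_S` / `qualifies_N` columns.
#'   When fewer than four macroalgal habitats were evaluated the result
#'   carries `restricted = TRUE` (as a column and attribute): "core" is
#'   then unattainable and categories refer to the evaluated subset only.
#' @export
classifyTaxa <- function(qualifies, cfg = phycoConfig()) {
  stopifnot(all(c("taxon", "habitat", "qualifies") %in% colnames(qualifies)))
  taxa <- unique(qualifies$taxon)
  macro <- intersect(.MACROALGAL, unique(qualifies$habitat))
  restricted <- length(macro) < 4L
  if (restricted)
    warning("only ", length(macro),
            " macroalgal habitat(s) evaluated; categories are restricted")
  qm <- qualifies[qualifies$habitat %in% macro, , drop = FALSE]
  counts <- vapply(taxa, function(tx)
    sum(qm$qualifies[qm$taxon == tx]), integer(1))
  category <- ifelse(counts == 4L, "core",
              ifelse(counts == 3L, "dominant",
              ifelse(counts >= 1L, "host_specific", "background")))
  out <- data.frame(taxon = taxa, n_macroalgal = counts,
                    category = category, restricted = restricted,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (ctrl in intersect(c("S", "N"), unique(qualifies$habitat))) {
    qc <- qualifies[qualifies$habitat == ctrl, , drop = FALSE]
    out[[paste0("qualifies_", ctrl)]] <-
      qc$qualifies[match(taxa, qc$taxon)]
  }
  attr(out, "restricted") <- restricted
  out
}

#' Mean total abundance of a taxon category per habitat
#'
#' For each habitat, sums the abundances of all taxa of the requested
#' category within each sample, then averages those per-sample totals
#' across the habitat's samples. Also reports the mean of the macroalgal
#' habitat means (the cross-host average).
#'
#' @param table an [AbundanceTable-class].
#' @param statuses output of [classifyTaxa()], or any data.frame with
#'   `taxon` and `category` columns.
#' @param category category to summarize (default `"core"`).
#' @return A data.frame `habitat`, `n_samples`, `mean_total` (percent),
#'   with the cross-habitat macroalgal mean in
#'   `attr(, "macroalgal_mean")`.
#' @export
summarizeCategoryAbundance <- function(table, statuses, category = "core") {
  stopifnot(is(table, "AbundanceTable"))
  sel <- statuses$taxon[statuses$category == category]
  v <- abundances(table)
  hab <- as.character(colData(table)$habitat)
  vs <- v[rownames(v) %in% sel, , drop = FALSE]
  totals <- colSums(vs)
  habs <- intersect(.HABITATS, unique(hab))
  out <- data.frame(
    habitat = habs,
    n_samples = vapply(habs, function(h) sum(hab == h), integer(1)),
    mean_total = vapply(habs, function(h) mean(totals[hab == h]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  macro <- out$habitat %in% .MACROALGAL
  attr(out, "macroalgal_mean") <- mean(out$mean_total[macro])
  out
}

#' Alpha diversity of a count vector
#'
#' Shannon index in nats (natural log), Simpson diversity `1 - sum(p^2)`
#' and Good's coverage `1 - F1/N` (F1 = singleton taxa, N = total reads).
#'
#' @param counts non-negative integer vector of per-taxon read counts.
#' @return A data.frame with columns `shannon`, `simpson`,
#'   `goods_coverage`.
#' @examples
#' alphaDiversity(c(10, 10, 10, 10))  # shannon = log(4), simpson = 0.75
#' @export
alphaDiversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("total count must be >= 1")
  data.frame(
    shannon = unname(vegan::diversity(counts, index = "shannon")),
    simpson = unname(vegan::diversity(counts, index = "simpson")),
    goods_coverage = 1 - sum(counts == 1) / n)
}

#' Expected rarefaction richness
#'
#' Expected number of taxa observed in a random subsample of `d` reads,
#' computed with the hypergeometric closed form
#' `E[S_d] = sum_i (1 - choose(N - n_i, d) / choose(N, d))`
#' (via [vegan::rarefy()]).
#'
#' @param counts non-negative integer count vector.
#' @param depths subsampling depths, each `<= sum(counts)`.
#' @return A data.frame `depth`, `expected_richness`.
#' @export
rarefactionCurve <- function(counts, depths) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("total count must be >= 1")
  depths <- as.integer(depths)
  if (any(depths > n)) stop("depth exceeds total count")
  if (any(depths < 1)) stop("depths must be >= 1")
  er <- vapply(depths, function(d)
    unname(vegan::rarefy(counts, sample = d)), numeric(1))
  data.frame(depth = depths, expected_richness = er)
}

#' Greedy centroid clustering of a 16S identity matrix
#'
#' UCLUST-style greedy clustering: items are processed in decreasing order
#' of their number of neighbours at `>= threshold` identity (ties broken by
#' input order); an item joins the first existing centroid it matches at
#' `>= threshold`, otherwise it founds a new cluster. Every member is
#' therefore guaranteed `>= threshold` identity to its cluster centroid.
#'
#' @param identity symmetric percent identity matrix, diagonal 100.
#' @param threshold percent identity threshold (e.g. 98.7 for species,
#'   94.5 for genera).
#' @return A list with `membership` (integer cluster per item),
#'   `centroids` (item index of each cluster centroid) and `n_clusters`.
#' @export
cluster16S <- function(identity, threshold) {
  identity <- as.matrix(identity)
  if (nrow(identity) != ncol(identity) ||
      max(abs(identity - t(identity))) > 1e-9)
    stop("identity matrix must be symmetric")
  n <- nrow(identity)
  deg <- rowSums(identity >= threshold)
  ord <- order(-deg, seq_len(n))
  membership <- integer(n)
  centroids <- integer(0)
  for (i in ord) {
    hit <- which(identity[i, centroids] >= threshold)
    if (length(hit)) {
      membership[i] <- hit[1L]
    } else {
      centroids <- c(centroids, i)
      membership[i] <- length(centroids)
    }
  }
  names(membership) <- rownames(identity)
  list(membership = membership, centroids = centroids,
       n_clusters = length(centroids))
}

#' Species- and genus-level partitions of a 16S identity matrix
#'
#' Convenience wrapper running [cluster16S()] at the configured species
#' (98.7%) and genus (94.5%) identity thresholds.
#'
#' @param identity symmetric percent identity matrix.
#' @param cfg a [PhycoConfig-class].
#' @return A list with elements `species` and `genus`, each a
#'   [cluster16S()] result.
#' @export
cluster16STaxa <- function(identity, cfg = phycoConfig()) {
  list(species = cluster16S(identity, cfg@speciesIdentity16S),
       genus = cluster16S(identity, cfg@genusIdentity16S))
}

#' Match cultured strains to amplicon ASVs and estimate cultivability
#'
#' A strain matches every ASV with 16S identity at or above the species
#' threshold (one-to-many assignments allowed). Cultivability is the
#' fraction of ASVs having at least one strain at or above the
#' cultivability threshold (97% by default).
#'
#' @param identity strains x ASVs percent identity matrix with dimnames.
#' @param cfg a [PhycoConfig-class].
#' @return A list: `matches` (data.frame `strain`, `asv`, `identity` for
#'   all pairs at `>= speciesIdentity16S`), `n_strains_matched`,
#'   `n_asvs_matched`, and `cultivability` (fraction of ASVs culturable).
#' @export
matchStrains <- function(identity, cfg = phycoConfig()) {
  identity <- as.matrix(identity)
  if (is.null(rownames(identity)))
    rownames(identity) <- paste0("strain", seq_len(nrow(identity)))
  if (is.null(colnames(identity)))
    colnames(identity) <- paste0("asv", seq_len(ncol(identity)))
  hit <- which(identity >= cfg@speciesIdentity16S, arr.ind = TRUE)
  matches <- data.frame(
    strain = rownames(identity)[hit[, 1L]],
    asv = colnames(identity)[hit[, 2L]],
    identity = identity[hit],
    row.names = NULL, stringsAsFactors = FALSE)
  matches <- matches[order(matches$strain, matches$asv), , drop = FALSE]
  rownames(matches) <- NULL
  cultivable <- apply(identity >= cfg@cultivabilityIdentity, 2L, any)
  list(matches = matches,
       n_strains_matched = length(unique(matches$strain)),
       n_asvs_matched = length(unique(matches$asv)),
       cultivability = mean(cultivable))
}
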