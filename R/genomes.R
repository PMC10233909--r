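.TIERS <- c("high", "nearly_complete", "medium", "reject")

#' Assign genome quality tiers
#'
#' Fixed evaluation order over CheckM-style metrics:
#' \enumerate{
#'   \item `high`: completeness >= 90, contamination < 5, complete rRNA
#'     operon and >= 18 tRNAs (MIMAG high quality);
#'   \item `nearly_complete`: completeness > 90 and contamination < 5
#'     (the "nearly complete" tier for genomes missing the rRNA/tRNA
#'     requirements);
#'   \item `medium`: completeness >= 50 and contamination < 10 (the
#'     retention floor);
#'   \item `reject`: everything below.
#' }
#'
#' @param quality data.frame with columns `genome_id`, `completeness`,
#'   `contamination` (percent) and optionally `n_trna`,
#'   `rrna_operon_complete` (missing values are treated as not fulfilling
#'   the high-quality extras).
#' @param cfg a [PhycoConfig-class]; cutoffs from `qualityCutoffs`.
#' @return The input data.frame with a `tier` factor column
#'   (`high` > `nearly_complete` > `medium` > `reject`).
#' @export
assignQualityTier <- function(quality, cfg = phycoConfig()) {
  stopifnot(all(c("genome_id", "completeness", "contamination") %in%
                colnames(quality)))
  if (any(quality$completeness < 0 | quality$completeness > 100 |
          quality$contamination < 0 | quality$contamination > 100))
    stop("completeness/contamination must lie in [0, 100]")
  qc <- cfg@qualityCutoffs
  ntrna <- if (is.null(quality$n_trna)) rep(0L, nrow(quality))
           else ifelse(is.na(quality$n_trna), 0L, quality$n_trna)
  rrna <- if (is.null(quality$rrna_operon_complete))
            rep(FALSE, nrow(quality))
          else isTRUE_v(quality$rrna_operon_complete)
  comp <- quality$completeness
  cont <- quality$contamination
  tier <- ifelse(
    comp >= qc$high_completeness & cont < qc$high_contamination &
      rrna & ntrna >= qc$high_min_trna, "high",
    ifelse(comp > qc$nearly_completeness & cont < qc$nearly_contamination,
           "nearly_complete",
    ifelse(comp >= qc$medium_completeness & cont < qc$medium_contamination,
           "medium", "reject")))
  quality$tier <- factor(tier, levels = .TIERS)
  quality
}

# vectorized truthiness tolerant of 0/1, logical and NA
isTRUE_v <- function(x) {
  x <- as.logical(x)
  !is.na(x) & x
}

#' Dereplicate genomes from an ANI matrix
#'
#' Species clusters are the connected components of the graph with an edge
#' wherever ANI >= `aniSpecies` (95%) and aligned fraction >=
#' `aniAlignmentMin` (0.65). Within each cluster the representative is the
#' genome with the highest dRep-style score `completeness - 5 *
#' contamination` (ties by genome id), and the non-redundant set is built
#' greedily in decreasing score order so that no two retained genomes
#' share ANI >= `aniRedundancy` (99%).
#'
#' @param ani an [ANIMatrix-class].
#' @param quality data.frame with `genome_id`, `completeness`,
#'   `contamination` covering every genome in `ani` (a missing record is a
#'   hard error).
#' @param cfg a [PhycoConfig-class].
#' @return A list: `clusters` (data.frame `genome_id`, `cluster`),
#'   `representatives` (one genome id per cluster), `nonredundant`
#'   (character vector; representatives are always included).
#' @export
dereplicateGenomes <- function(ani, quality, cfg = phycoConfig()) {
  stopifnot(is(ani, "ANIMatrix"))
  validObject(ani)
  ids <- genomeIds(ani)
  miss <- setdiff(ids, quality$genome_id)
  if (length(miss))
    stop("genome(s) missing a quality record: ", paste(miss, collapse = ", "))
  a <- aniValues(ani)
  f <- alignFractions(ani)
  adj <- (a >= cfg@aniSpecies) & (f >= cfg@aniAlignmentMin)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  score <- setNames(
    quality$completeness - 5 * quality$contamination, quality$genome_id)[ids]
  clusters <- data.frame(genome_id = ids, cluster = as.integer(comp),
                         row.names = NULL, stringsAsFactors = FALSE)
  reps <- character(0)
  nonred <- character(0)
  for (k in sort(unique(comp))) {
    members <- ids[comp == k]
    o <- order(-score[members], members)
    members <- members[o]
    reps[as.character(k)] <- members[1L]
    kept <- character(0)
    for (m in members) {
      if (!length(kept) || all(a[m, kept] < cfg@aniRedundancy))
        kept <- c(kept, m)
    }
    nonred <- c(nonred, kept)
  }
  list(clusters = clusters, representatives = unname(reps),
       nonredundant = nonred)
}

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
            "species")

#' Reconcile multi-source taxonomic assignments
#'
#' Rank-by-rank consensus from domain down to species over GTDB-, SILVA-
#' and EzTaxon-style lineages. At each rank, sources reporting a value are
#' compared: unanimous agreement is accepted; with three or more sources a
#' value shared by at least two wins (majority rule); a two-source
#' disagreement without a tie-breaker is resolved in favour of the
#' preferred source (GTDB by default, the primary classifier) and flagged
#' as a conflict, or -- with `prefer = "none"` -- left unresolved. Rank
#' filling stops at the first unresolved rank, so the output lineage is
#' always a rank prefix.
#'
#' @param assignments data.frame with columns `genome_id`, `source` (e.g.
#'   `GTDB`, `SILVA`, `EZTAXON`) and the seven rank columns
#'   `domain`...`species` (empty string or NA for unassigned ranks).
#' @param has_16s logical flag recorded with each genome (per-genome vector
#'   recycled as needed); kept for provenance, the consensus rule itself is
#'   identical either way.
#' @param prefer `"GTDB"` (default) or `"none"`: how to resolve two-source
#'   conflicts.
#' @return A list with `consensus` (data.frame `genome_id` + rank columns)
#'   and `conflicts` (data.frame `genome_id`, `rank`, `values`,
#'   `resolved`).
#' @export
reconcileTaxonomy <- function(assignments, has_16s = TRUE,
                              prefer = c("GTDB", "none")) {
  prefer <- match.arg(prefer)
  stopifnot(all(c("genome_id", "source") %in% colnames(assignments)),
            all(.RANKS %in% colnames(assignments)))
  gids <- unique(assignments$genome_id)
  cons <- list()
  confl <- list()
  for (gid in gids) {
    sub <- assignments[assignments$genome_id == gid, , drop = FALSE]
    lineage <- setNames(rep(NA_character_, length(.RANKS)), .RANKS)
    for (rk in .RANKS) {
      vals <- as.character(sub[[rk]])
      src <- as.character(sub$source)
      keep <- !is.na(vals) & nzchar(vals)
      vals <- vals[keep]; src <- src[keep]
      if (!length(vals)) break  # no source reaches this rank
      uv <- unique(vals)
      if (length(uv) == 1L) {
        lineage[rk] <- uv
        next
      }
      counts <- table(vals)
      top <- names(counts)[counts == max(counts)]
      if (length(vals) >= 3L && length(top) == 1L && max(counts) >= 2L) {
        lineage[rk] <- top
        confl[[length(confl) + 1L]] <- data.frame(
          genome_id = gid, rank = rk,
          values = paste(sprintf("%s=%s", src, vals), collapse = ";"),
          resolved = "majority", stringsAsFactors = FALSE)
        next
      }
      if (prefer == "GTDB" && "GTDB" %in% src) {
        lineage[rk] <- vals[src == "GTDB"][1L]
        confl[[length(confl) + 1L]] <- data.frame(
          genome_id = gid, rank = rk,
          values = paste(sprintf("%s=%s", src, vals), collapse = ";"),
          resolved = "prefer_GTDB", stringsAsFactors = FALSE)
        next
      }
      confl[[length(confl) + 1L]] <- data.frame(
        genome_id = gid, rank = rk,
        values = paste(sprintf("%s=%s", src, vals), collapse = ";"),
        resolved = "unresolved", stringsAsFactors = FALSE)
      break  # prefix rule: stop at first unresolved conflict
    }
    cons[[gid]] <- c(genome_id = gid, lineage)
  }
  consensus <- as.data.frame(do.call(rbind, cons), stringsAsFactors = FALSE)
  rownames(consensus) <- NULL
  conflicts <- if (length(confl)) do.call(rbind, confl)
               else data.frame(genome_id = character(), rank = character(),
                               values = character(), resolved = character())
  list(consensus = consensus, conflicts = conflicts)
}

#' Summarize biosynthetic gene cluster records
#'
#' Per-class percentages of all BGC records (summing to 100 within
#' rounding) and the fraction of clusters lying on a contig edge
#' (potentially incomplete), overall and per genome-source group when a
#' `source` column (e.g. DG/MAG) is present.
#'
#' @param records data.frame with columns `genome_id`, `contig_id`,
#'   `bgc_class`, `on_contig_edge` (logical or 0/1) and optionally
#'   `source`.
#' @return A list: `classes` (data.frame `bgc_class`, `n`, `percent`),
#'   `edge_fraction` (overall), `edge_by_source` (data.frame, `NULL`
#'   without a source column).
#' @export
summarizeBGCs <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(list(classes = data.frame(bgc_class = character(), n = integer(),
                                     percent = numeric()),
                edge_fraction = NA_real_, edge_by_source = NULL))
  }
  stopifnot(all(c("bgc_class", "on_contig_edge") %in% colnames(records)))
  edge <- isTRUE_v(records$on_contig_edge)
  tab <- sort(table(records$bgc_class), decreasing = TRUE)
  classes <- data.frame(bgc_class = names(tab), n = as.integer(tab),
                        percent = 100 * as.integer(tab) / nrow(records),
                        row.names = NULL, stringsAsFactors = FALSE)
  edge_by_source <- NULL
  if (!is.null(records$source)) {
    srcs <- unique(records$source)
    edge_by_source <- data.frame(
      source = srcs,
      n = vapply(srcs, function(s) sum(records$source == s), integer(1)),
      edge_fraction = vapply(srcs, function(s)
        mean(edge[records$source == s]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  list(classes = classes, edge_fraction = mean(edge),
       edge_by_source = edge_by_source)
}
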