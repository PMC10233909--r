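#' Ordered CAZyme-composition profiles of detected loci
#'
#' Extracts, for each locus of the requested categories, its ordered
#' CAZyme-family string (subfamily labels such as `GH5_2` kept distinct),
#' sulfatase count and deacetylase flag (any CE4 family present). These
#' profiles are the substrate of [clusterPULs()] and [inferSubstrates()].
#'
#' @param x a [LocusSet-class].
#' @param include categories to profile; default `PUL`, `PUL_like` and
#'   `CGC` (all categories with a non-empty composition).
#' @return A [S4Vectors::DataFrame] with columns `locus_id`, `genome_id`,
#'   `category`, `cazy_string` (`CharacterList`), `sulfatase_count`,
#'   `deacetylase_flag`.
#' @export
pulProfiles <- function(x, include = c("PUL", "PUL_like", "CGC")) {
  stopifnot(is(x, "LocusSet"))
  l <- x@loci[x@loci$category %in% include, , drop = FALSE]
  S4Vectors::DataFrame(
    locus_id = sprintf("%s:%s:%d", l$genome_id, l$contig_id, l$first_index),
    genome_id = l$genome_id,
    category = l$category,
    cazy_string = l$cazy_string,
    sulfatase_count = l$n_sulfatases,
    deacetylase_flag = vapply(l$cazy_string, function(f)
      any(sub("_.*$", "", f) == "CE4"), logical(1)))
}

#' Composition distance between two PUL profiles
#'
#' Longest-common-subsequence dissimilarity over the ordered family
#' strings: `d = 1 - 2 * LCS(a, b) / (|a| + |b|)`. Identical strings give
#' 0, label-disjoint strings 1; the distance is symmetric with
#' `d(x, x) = 0` but is a premetric only -- the triangle inequality is not
#' guaranteed for LCS-based dissimilarities.
#'
#' @param a,b non-empty character vectors of CAZyme family labels in gene
#'   order.
#' @return A dissimilarity in `[0, 1]`.
#' @examples
#' pulDistance(c("GH16", "GH3"), c("GH16", "GH3"))  # 0
#' pulDistance("GH16", "PL7")                       # 1
#' @export
pulDistance <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty PUL profile")
  na <- length(a); nb <- length(b)
  # classic O(na*nb) LCS dynamic programme
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  1 - 2 * prev[nb + 1L] / (na + nb)
}

#' Cluster PULs by CAZyme composition
#'
#' With the default distance cut of 0, clusters are exactly the groups of
#' loci with identical ordered family strings ("identical PULs");
#' singleton clusters are unique compositions. A non-zero cut performs
#' single-linkage agglomeration on [pulDistance()] and cuts the dendrogram
#' at that height.
#'
#' @param profiles a profile `DataFrame` from [pulProfiles()] (or a
#'   [LocusSet-class], profiled with defaults).
#' @param cfg a [PhycoConfig-class]; `pulClusterDistanceCut` selects the
#'   cut.
#' @return A list: `membership` (integer cluster id per profile),
#'   `sizes` (cluster size table) and `summary` with `n_clusters`,
#'   `n_clusters_ge2` (clusters holding at least two identical/linked
#'   PULs) and `n_clusters_gt10`.
#' @export
clusterPULs <- function(profiles, cfg = phycoConfig()) {
  if (is(profiles, "LocusSet")) profiles <- pulProfiles(profiles)
  strs <- as.list(profiles$cazy_string)
  n <- length(strs)
  if (n == 0L) {
    return(list(membership = integer(0), sizes = integer(0),
                summary = data.frame(n_clusters = 0L, n_clusters_ge2 = 0L,
                                     n_clusters_gt10 = 0L)))
  }
  cut <- cfg@pulClusterDistanceCut
  if (cut <= 0) {
    key <- vapply(strs, paste, "", collapse = "\r")
    membership <- match(key, unique(key))
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- pulDistance(strs[[i]], strs[[j]])
      }
    }
    membership <- unname(cutree(hclust(as.dist(d), method = "single"),
                                h = cut))
  }
  sizes <- table(membership)
  list(membership = membership,
       sizes = as.integer(sizes),
       summary = data.frame(
         n_clusters = length(sizes),
         n_clusters_ge2 = sum(sizes >= 2L),
         n_clusters_gt10 = sum(sizes > 10L)))
}

.validateRules <- function(rules) {
  for (r in rules) {
    if (is.null(r$rule_id) || is.null(r$substrate))
      stop("malformed substrate rule: rule_id and substrate are required")
    if (is.null(r$required_groups) || !length(r$required_groups))
      stop("malformed substrate rule '", r$rule_id,
           "': at least one required group")
    fams <- unlist(r$required_groups)
    if (any(!grepl(.FAMILY_RE, fams)))
      stop("malformed substrate rule '", r$rule_id,
           "': invalid family label")
  }
  rules
}

#' Load substrate inference rules
#'
#' Reads a YAML rule table mapping CAZyme-family compositions to candidate
#' polysaccharide substrates. Each rule has `rule_id`, `substrate`,
#' `required_groups` (a list of family groups; each group is satisfied by
#' any of its families, and all groups must be satisfied), optional
#' `exclusive` (no families outside the listed set allowed) and
#' `min_sulfatases`. `defaultSubstrateRules()` loads the table shipped
#' with the package, seeded with field-standard composition-substrate
#' mappings (GH3+GH16 for beta-glucans/laminarin, GH13+GH65 for
#' alpha-glucans, PL6/PL7/PL12/PL17 for alginate, exclusively-CE1/CE3/CE4
#' loci for xylose-containing polysaccharides, sulfatase-rich GH29/GH106
#' loci for FCSP/fucoidan, PL25/PL40 for ulvan).
#'
#' @param path YAML file.
#' @return A list of rule records (validated at load time; malformed rules
#'   are a hard error).
#' @export
readSubstrateRules <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- if (!is.null(y$rules)) y$rules else y
  rules <- lapply(rules, function(r) {
    r$required_groups <- lapply(r$required_groups, as.character)
    r$exclusive <- isTRUE(r$exclusive)
    r$min_sulfatases <- if (is.null(r$min_sulfatases)) 0L
                        else as.integer(r$min_sulfatases)
    r
  })
  .validateRules(rules)
}

#' @rdname readSubstrateRules
#' @export
defaultSubstrateRules <- function() {
  readSubstrateRules(system.file("extdata", "substrate_rules.yaml",
                                 package = "phycoPUL", mustWork = TRUE))
}

#' Infer candidate substrates for one locus composition
#'
#' Evaluates every rule against the locus: a rule fires when each of its
#' required groups contains at least one family present in the profile,
#' the sulfatase count reaches `min_sulfatases`, and -- for exclusive
#' rules -- no profile family lies outside the rule's listed set.
#' Subfamily labels match their parent family at rule-evaluation time
#' (`GH5_2` satisfies a rule asking for `GH5`). All satisfied rules fire;
#' larger loci may therefore receive multiple substrates.
#'
#' @param families character vector of CAZyme family labels (a locus
#'   `cazy_string`).
#' @param sulfatase_count number of sulfatase genes in the locus.
#' @param rules rule list from [readSubstrateRules()]; default the shipped
#'   table.
#' @return Character vector of substrate labels (names = rule ids); empty
#'   if no rule fires.
#' @examples
#' inferSubstrates(c("GH3", "GH16"))  # beta-glucan/laminarin
#' @export
inferSubstrates <- function(families, sulfatase_count = 0L,
                            rules = defaultSubstrateRules()) {
  base <- sub("_.*$", "", families)
  out <- character(0)
  for (r in rules) {
    groups_ok <- all(vapply(r$required_groups,
                            function(g) any(base %in% g), logical(1)))
    if (!groups_ok) next
    if (sulfatase_count < r$min_sulfatases) next
    if (r$exclusive && !all(base %in% unlist(r$required_groups))) next
    out[r$rule_id] <- r$substrate
  }
  out
}

#' Annotate a LocusSet with inferred substrates
#'
#' Runs [inferSubstrates()] over every locus and stores the resulting
#' labels in the `substrates` column.
#'
#' @param x a [LocusSet-class].
#' @param rules substrate rule list.
#' @return The annotated [LocusSet-class].
#' @export
annotateSubstrates <- function(x, rules = defaultSubstrateRules()) {
  stopifnot(is(x, "LocusSet"))
  l <- x@loci
  subs <- lapply(seq_len(nrow(l)), function(i)
    unname(inferSubstrates(l$cazy_string[[i]], l$n_sulfatases[i], rules)))
  l$substrates <- IRanges::CharacterList(subs)
  initialize(x, loci = l)
}

#' Count PULs per predicted substrate
#'
#' A locus ascribed to k substrates contributes to k rows; labels are
#' reported in deterministic (alphabetical) order.
#'
#' @param x a substrate-annotated [LocusSet-class] (see
#'   [annotateSubstrates()]) or a list/`CharacterList` of per-locus
#'   substrate label vectors.
#' @return A data.frame `substrate`, `n`.
#' @export
substrateSummary <- function(x) {
  subs <- if (is(x, "LocusSet")) as.list(x@loci$substrates) else as.list(x)
  lab <- unlist(subs, use.names = FALSE)
  if (!length(lab))
    return(data.frame(substrate = character(), n = integer()))
  tab <- table(lab)
  data.frame(substrate = names(tab)[order(names(tab))],
             n = as.integer(tab[order(names(tab))]),
             row.names = NULL, stringsAsFactors = FALSE)
}
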