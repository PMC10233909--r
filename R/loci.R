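.famClass <- function(f) sub("^(GH|GT|PL|CE|AA|CBM).*$", "\\1", f)

.isCazymeGene <- function(fams, markerClasses) {
  vapply(fams, function(f) any(.famClass(f) %in% markerClasses), logical(1))
}

#' Greedy adjacent susC-susD pairing over a role vector
#'
#' Scans roles in gene order and pairs a susC immediately followed by a
#' susD (with `orientation = "both"`, also susD then susC); each gene joins
#' at most one pair.
#'
#' @param roles character vector of role flags in gene-index order.
#' @param orientation `"CD"` or `"both"`.
#' @return Integer vector of pair start positions (1-based within `roles`).
#' @keywords internal
.susCDPairs <- function(roles, orientation = "CD") {
  n <- length(roles)
  starts <- integer(0)
  used <- logical(n)
  i <- 1L
  while (i < n) {
    ok <- !used[i] && !used[i + 1L] &&
      ((roles[i] == "susC" && roles[i + 1L] == "susD") ||
       (orientation == "both" &&
        roles[i] == "susD" && roles[i + 1L] == "susC"))
    if (ok) {
      starts <- c(starts, i)
      used[i] <- used[i + 1L] <- TRUE
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  starts
}

#' Classify a candidate locus into the four locus categories
#'
#' Category rules over the locus composition: `PUL` needs at least one
#' CAZyme gene and one complete susCD pair; `PUL_like` at least one CAZyme
#' and a susC or TonB-dependent receptor but no complete pair; `CGC` no
#' susC/susD/tonB at all and at least `cgcMinCazymes` CAZyme genes;
#' `susCD_only` at least one pair and zero CAZymes. Compositions matching
#' no category (e.g. a lone sulfatase, or one stray CAZyme without
#' receptor) return `NA` and are dropped by [detectLoci()] with a log
#' record.
#'
#' @param n_cazymes number of CAZyme genes in the locus.
#' @param n_pairs number of complete susCD pairs.
#' @param has_susC,has_susD,has_tonB receptor-gene presence flags.
#' @param cfg a [PhycoConfig-class].
#' @return One of `"PUL"`, `"PUL_like"`, `"CGC"`, `"susCD_only"`, or
#'   `NA_character_`.
#' @export
classifyLocusCategory <- function(n_cazymes, n_pairs, has_susC, has_susD,
                                  has_tonB, cfg = phycoConfig()) {
  if (n_cazymes >= 1L && n_pairs >= 1L) return("PUL")
  if (n_cazymes >= 1L && (has_susC || has_tonB)) return("PUL_like")
  if (!has_susC && !has_susD && !has_tonB &&
      n_cazymes >= cfg@cgcMinCazymes) return("CGC")
  if (n_pairs >= 1L && n_cazymes == 0L) return("susCD_only")
  NA_character_
}

#' Type the susCD architecture of a locus
#'
#' A pair is a susC immediately followed by a susD (adjacent gene
#' indices). Architectures: `single` (exactly one pair, no unpaired
#' susC/susD), `tandem_repeat` (two or more pairs with consecutive pairs
#' adjacent, ...C-D-C-D...), `hybrid` (at least one pair plus at least one
#' unpaired susC or susD inside the locus), `tandem_repeat_hybrid` (both),
#' and `none` for anything else. Only meaningful for `PUL` and
#' `susCD_only` loci.
#'
#' @param roles character vector of role flags in gene-index order over
#'   the locus span.
#' @param orientation pair orientation rule, see [PhycoConfig-class].
#' @return Architecture label.
#' @examples
#' typeArchitecture(c("susC", "susD", "none"))                   # single
#' typeArchitecture(c("susC", "susD", "susC", "susD"))           # tandem_repeat
#' typeArchitecture(c("susC", "susD", "susC", "susD", "susC"))   # tandem_repeat_hybrid
#' @export
typeArchitecture <- function(roles, orientation = "CD") {
  starts <- .susCDPairs(roles, orientation)
  npairs <- length(starts)
  if (npairs == 0L) return("none")
  paired <- unlist(lapply(starts, function(s) c(s, s + 1L)))
  unpaired <- setdiff(which(roles %in% c("susC", "susD")), paired)
  tandem <- npairs >= 2L && any(diff(starts) == 2L)
  hybrid <- length(unpaired) > 0L
  if (tandem && hybrid) return("tandem_repeat_hybrid")
  if (tandem) return("tandem_repeat")
  if (hybrid) return("hybrid")
  if (npairs == 1L) return("single")
  "none"  # >= 2 well-separated pairs, no unpaired genes
}

#' Detect candidate polysaccharide-degradation loci
#'
#' Per contig, marker genes (genes with a CAZyme family from the
#' configured catabolic classes, or flagged susC, susD, tonB or sulfatase)
#' are chained into one locus whenever two consecutive markers are
#' separated by fewer than `windowGenes` intervening genes -- a sliding
#' window of ten genes by default. A locus spans from its first to its
#' last marker gene; loci never cross contigs, and each marker belongs to
#' exactly one locus. Chained candidates are then classified
#' ([classifyLocusCategory()]) and PUL / susCD-only loci architecture-typed
#' ([typeArchitecture()]); candidates matching no category go to the
#' dropped log.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param cfg a [PhycoConfig-class].
#' @return A [LocusSet-class].
#' @export
detectLoci <- function(annotation, cfg = phycoConfig()) {
  stopifnot(is(annotation, "GenomeAnnotation"))
  validObject(annotation)
  g <- annotation@genes
  rows <- list()
  drops <- list()
  for (ct in unique(g$contig_id)) {
    sub <- g[g$contig_id == ct, , drop = FALSE]
    if (is.unsorted(sub$gene_index)) stop("unsorted annotation")
    caz <- .isCazymeGene(sub$cazy_families, cfg@markerClasses)
    marker <- caz | sub$role %in% c("susC", "susD", "tonB", "sulfatase")
    m <- which(marker)
    if (!length(m)) next
    grp <- cumsum(c(1L, as.integer(diff(m) - 1L >= cfg@windowGenes)))
    for (k in unique(grp)) {
      mk <- m[grp == k]
      span <- seq(min(mk), max(mk))
      roles <- sub$role[span]
      ncaz <- sum(caz[span])
      starts <- .susCDPairs(roles, cfg@pairOrientation)
      cat_ <- classifyLocusCategory(
        ncaz, length(starts),
        any(roles == "susC"), any(roles == "susD"), any(roles == "tonB"),
        cfg)
      first_ix <- sub$gene_index[min(mk)]
      last_ix <- sub$gene_index[max(mk)]
      if (is.na(cat_)) {
        drops[[length(drops) + 1L]] <- data.frame(
          genome_id = annotation@genomeId, contig_id = ct,
          first_index = first_ix, last_index = last_ix,
          reason = "no category matched", stringsAsFactors = FALSE)
        next
      }
      arch <- if (cat_ %in% c("PUL", "susCD_only"))
        typeArchitecture(roles, cfg@pairOrientation) else "none"
      fams <- unlist(sub$cazy_families[span][caz[span]], use.names = FALSE)
      rows[[length(rows) + 1L]] <- list(
        genome_id = annotation@genomeId, contig_id = ct,
        first_index = first_ix, last_index = last_ix,
        n_genes = length(span), category = cat_, architecture = arch,
        n_cazymes = as.integer(ncaz), n_susCD_pairs = length(starts),
        n_sulfatases = sum(roles == "sulfatase"),
        cazyme_density = ncaz / length(span),
        cazy_string = if (is.null(fams)) character(0) else fams,
        gene_ids = sub$gene_id[span])
    }
  }
  if (!length(rows)) {
    return(LocusSet(dropped = if (length(drops))
      S4Vectors::DataFrame(do.call(rbind, drops)) else NULL))
  }
  df <- S4Vectors::DataFrame(
    genome_id = vapply(rows, `[[`, "", "genome_id"),
    contig_id = vapply(rows, `[[`, "", "contig_id"),
    first_index = vapply(rows, `[[`, 1L, "first_index"),
    last_index = vapply(rows, `[[`, 1L, "last_index"),
    n_genes = vapply(rows, `[[`, 1L, "n_genes"),
    category = vapply(rows, `[[`, "", "category"),
    architecture = vapply(rows, `[[`, "", "architecture"),
    n_cazymes = vapply(rows, `[[`, 1L, "n_cazymes"),
    n_susCD_pairs = vapply(rows, `[[`, 1L, "n_susCD_pairs"),
    n_sulfatases = vapply(rows, `[[`, 1L, "n_sulfatases"),
    cazyme_density = vapply(rows, `[[`, 1.0, "cazyme_density"),
    cazy_string = IRanges::CharacterList(lapply(rows, `[[`, "cazy_string")),
    gene_ids = IRanges::CharacterList(lapply(rows, `[[`, "gene_ids")),
    substrates = IRanges::CharacterList(rep(list(character(0)), length(rows))))
  LocusSet(df, dropped = if (length(drops))
    S4Vectors::DataFrame(do.call(rbind, drops)) else NULL)
}

#' Summary statistics over a set of loci
#'
#' Per category: locus count, fraction containing at least one sulfatase
#' gene, mean and maximum locus length (in genes), and mean CAZyme
#' density. Per genome: PUL count and -- when the source annotations are
#' supplied -- the percentage of the genome's CAZyme genes residing inside
#' PULs.
#'
#' @param x a [LocusSet-class].
#' @param annotations optional named list of [GenomeAnnotation-class]
#'   objects (names = genome ids) for genome-wide CAZyme totals.
#' @param cfg a [PhycoConfig-class] (marker classes for CAZyme counting).
#' @return A list with data.frames `categories` and `genomes`.
#' @export
locusStatistics <- function(x, annotations = NULL, cfg = phycoConfig()) {
  stopifnot(is(x, "LocusSet"))
  l <- x@loci
  cats <- .CATEGORIES
  categories <- data.frame(
    category = cats,
    n = vapply(cats, function(cc) sum(l$category == cc), integer(1)),
    sulfatase_fraction = vapply(cats, function(cc) {
      i <- l$category == cc
      if (!any(i)) return(0)
      mean(l$n_sulfatases[i] >= 1L)
    }, numeric(1)),
    mean_length = vapply(cats, function(cc) {
      i <- l$category == cc
      if (!any(i)) return(0)
      mean(l$n_genes[i])
    }, numeric(1)),
    max_length = vapply(cats, function(cc) {
      i <- l$category == cc
      if (!any(i)) return(0L)
      as.integer(max(l$n_genes[i]))
    }, integer(1)),
    mean_cazyme_density = vapply(cats, function(cc) {
      i <- l$category == cc
      if (!any(i)) return(0)
      mean(l$cazyme_density[i])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  gids <- unique(l$genome_id)
  genomes <- data.frame(
    genome_id = gids,
    n_pul = vapply(gids, function(gg)
      sum(l$genome_id == gg & l$category == "PUL"), integer(1)),
    pct_cazymes_in_pul = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    for (i in seq_along(genomes$genome_id)) {
      gid <- genomes$genome_id[i]
      ann <- annotations[[gid]]
      if (is.null(ann)) next
      total <- sum(.isCazymeGene(ann@genes$cazy_families, cfg@markerClasses))
      inpul <- sum(l$n_cazymes[l$genome_id == gid & l$category == "PUL"])
      genomes$pct_cazymes_in_pul[i] <-
        if (total > 0) 100 * inpul / total else NA_real_
    }
  }
  list(categories = categories, genomes = genomes)
}

#' Signal-peptide fractions per CAZyme class
#'
#' For each CAZyme class (GH, GT, PL, CE, AA, CBM), the fraction of genes
#' carrying at least one family of that class that are flagged with a
#' signal peptide. A gene with families from k classes counts once in each
#' of the k classes.
#'
#' @param annotation a [GenomeAnnotation-class] (or list of them, pooled).
#' @return A data.frame `class`, `n_genes`, `n_secreted`, `fraction`;
#'   classes with no genes are omitted.
#' @export
secretionSummary <- function(annotation) {
  anns <- if (is(annotation, "GenomeAnnotation")) list(annotation)
          else annotation
  fams <- do.call(c, lapply(anns, function(a) as.list(a@genes$cazy_families)))
  sp <- unlist(lapply(anns, function(a) a@genes$signal_peptide))
  rows <- lapply(.CAZY_CLASSES, function(cl) {
    carries <- vapply(fams, function(f) any(.famClass(f) == cl), logical(1))
    if (!any(carries)) return(NULL)
    data.frame(class = cl, n_genes = sum(carries),
               n_secreted = sum(sp[carries]),
               fraction = mean(sp[carries]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class = character(), n_genes = integer(),
                      n_secreted = integer(), fraction = numeric())
  rownames(out) <- NULL
  out
}
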