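#' A set of detected polysaccharide-degradation loci
#'
#' Result container of [detectLoci()]. Each row of `loci` is one detected
#' locus with its category -- `PUL` (CAZymes plus at least one complete
#' susCD pair), `PUL_like` (CAZymes plus a susC/TonB receptor but no
#' complete pair), `CGC` (CAZyme-rich cluster without any receptor) or
#' `susCD_only` (pairs without detectable CAZymes) -- its susCD
#' architecture (`single`, `tandem_repeat`, `hybrid`,
#' `tandem_repeat_hybrid`, `none`) and composition statistics. Candidate
#' loci that fit no category (e.g. a lone sulfatase) are logged in the
#' `dropped` slot, not silently discarded.
#'
#' @slot loci [S4Vectors::DataFrame] with columns `genome_id`, `contig_id`,
#'   `first_index`, `last_index`, `n_genes`, `category`, `architecture`,
#'   `n_cazymes`, `n_susCD_pairs`, `n_sulfatases`, `cazyme_density`,
#'   `cazy_string` (`CharacterList`, family labels in gene order),
#'   `gene_ids` (`CharacterList`), `substrates` (`CharacterList`).
#' @slot dropped `DataFrame` logging candidate loci that matched no
#'   category, with a `reason` column.
#' @export
setClass("LocusSet",
  representation(loci = "DataFrame", dropped = "DataFrame"))

.LOCUS_COLS <- c("genome_id", "contig_id", "first_index", "last_index",
                 "n_genes", "category", "architecture", "n_cazymes",
                 "n_susCD_pairs", "n_sulfatases", "cazyme_density",
                 "cazy_string", "gene_ids", "substrates")
.CATEGORIES <- c("PUL", "PUL_like", "CGC", "susCD_only")
.ARCHITECTURES <- c("single", "tandem_repeat", "hybrid",
                    "tandem_repeat_hybrid", "none")

setValidity("LocusSet", function(object) {
  l <- object@loci
  if (!all(.LOCUS_COLS %in% colnames(l)))
    return(paste("loci must have columns:", paste(.LOCUS_COLS, collapse = ", ")))
  if (nrow(l) == 0L) return(TRUE)
  msg <- character()
  if (!all(l$category %in% .CATEGORIES)) msg <- c(msg, "invalid category")
  if (!all(l$architecture %in% .ARCHITECTURES))
    msg <- c(msg, "invalid architecture")
  if (any(l$first_index > l$last_index)) msg <- c(msg, "inverted locus span")
  if (any(abs(l$cazyme_density - l$n_cazymes / l$n_genes) > 1e-9))
    msg <- c(msg, "cazyme_density must equal n_cazymes / n_genes")
  if (length(msg)) msg else TRUE
})

.emptyLocusDF <- function() {
  S4Vectors::DataFrame(
    genome_id = character(), contig_id = character(),
    first_index = integer(), last_index = integer(), n_genes = integer(),
    category = character(), architecture = character(),
    n_cazymes = integer(), n_susCD_pairs = integer(),
    n_sulfatases = integer(), cazyme_density = numeric(),
    cazy_string = IRanges::CharacterList(),
    gene_ids = IRanges::CharacterList(),
    substrates = IRanges::CharacterList())
}

#' Construct a LocusSet
#'
#' Usually produced by [detectLoci()]; the constructor is exported for
#' programmatic assembly (e.g. when re-reading a locus report).
#'
#' @param loci `DataFrame` or data.frame of locus records (see
#'   [LocusSet-class]); list columns may be given as semicolon strings.
#' @param dropped optional log of rejected candidate loci.
#' @return A [LocusSet-class].
#' @export
LocusSet <- function(loci = .emptyLocusDF(), dropped = NULL) {
  if (!is(loci, "DataFrame")) loci <- S4Vectors::DataFrame(loci)
  for (col in c("cazy_string", "gene_ids", "substrates")) {
    if (!is(loci[[col]], "CharacterList")) {
      v <- loci[[col]]
      if (!is.list(v)) {
        v <- strsplit(as.character(v), ";", fixed = TRUE)
        v <- lapply(v, function(f) f[nzchar(f)])
      }
      loci[[col]] <- IRanges::CharacterList(v)
    }
  }
  if (is.null(dropped))
    dropped <- S4Vectors::DataFrame(genome_id = character(),
                                    contig_id = character(),
                                    first_index = integer(),
                                    last_index = integer(),
                                    reason = character())
  new("LocusSet", loci = loci, dropped = dropped)
}

#' Accessor for the locus table of a LocusSet
#'
#' @param x a [LocusSet-class]
#' @return the `DataFrame` of loci; `droppedLoci()` the rejection log.
#' @export
loci <- function(x) {
  stopifnot(is(x, "LocusSet"))
  x@loci
}

#' @rdname loci
#' @export
droppedLoci <- function(x) {
  stopifnot(is(x, "LocusSet"))
  x@dropped
}

#' @describeIn LocusSet-class number of loci
#' @param x a `LocusSet`
#' @export
setMethod("length", "LocusSet", function(x) nrow(x@loci))

#' @describeIn LocusSet-class category breakdown
#' @param object a `LocusSet`
#' @export
setMethod("show", "LocusSet", function(object) {
  l <- object@loci
  cat(sprintf("LocusSet: %d loci (%d dropped candidates)\n",
              nrow(l), nrow(object@dropped)))
  if (nrow(l)) {
    tab <- table(factor(l$category, levels = .CATEGORIES))
    cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
})
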