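#' Taxa-by-sample relative abundance table
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one `"abundance"` assay of relative abundances in percent (taxa in rows,
#' samples in columns) with per-sample metadata (`habitat`, `season`,
#' `replicate`) in `colData`. Habitat codes follow the survey design:
#' H = *Gelidium* sp., R = *Grateloupia* sp., L = *Ulva* sp.,
#' B = *Saccharina* sp., S = seawater, N = sediment; seasons are coded 1-4.
#'
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  v <- assay(object, "abundance")
  if (any(v < 0)) msg <- c(msg, "abundances must be non-negative")
  cs <- colSums(v)
  if (any(cs > 100 + 1e-6))
    msg <- c(msg, "per-sample abundance sums must not exceed 100")
  cd <- colData(object)
  if (!all(c("habitat", "season") %in% colnames(cd)))
    return("colData must contain 'habitat' and 'season'")
  if (!all(as.character(cd$habitat) %in% .HABITATS))
    msg <- c(msg, sprintf("habitat codes must be in {%s}",
                          paste(.HABITATS, collapse = ",")))
  if (!all(as.integer(cd$season) %in% 1:4))
    msg <- c(msg, "season codes must be in {1,2,3,4}")
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric matrix, taxa x samples, relative abundances in
#'   percent. Row and column names are taxon and sample ids.
#' @param sampleMeta data.frame with one row per sample and columns
#'   `sample_id`, `habitat`, `season` and optionally `replicate`; matched to
#'   the columns of `values` by `sample_id`.
#' @param rowData optional data.frame of per-taxon annotation (e.g. rank
#'   labels or category flags).
#'
#' @return An [AbundanceTable-class] object.
#' @examples
#' v <- matrix(c(60, 40, 30, 70), 2, dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' m <- data.frame(sample_id = c("s1", "s2"), habitat = "H", season = 1)
#' AbundanceTable(v, m)
#' @export
AbundanceTable <- function(values, sampleMeta, rowData = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("'values' must have sample ids as column names")
  idx <- match(colnames(values), sampleMeta$sample_id)
  if (anyNA(idx)) {
    orphans <- colnames(values)[is.na(idx)]
    stop("sample(s) without metadata: ", paste(orphans, collapse = ", "))
  }
  cd <- S4Vectors::DataFrame(sampleMeta[idx, , drop = FALSE])
  rownames(cd) <- colnames(values)
  cd$habitat <- as.character(cd$habitat)
  cd$season <- as.integer(cd$season)
  se <- SummarizedExperiment(
    assays = list(abundance = values),
    colData = cd,
    rowData = if (is.null(rowData)) NULL else S4Vectors::DataFrame(rowData)
  )
  new("AbundanceTable", se)
}

#' Accessors for AbundanceTable
#'
#' `abundances()` returns the taxa-by-sample percent matrix; `sampleMeta()`
#' the per-sample metadata as a `DataFrame`.
#'
#' @param x an [AbundanceTable-class]
#' @return a matrix or `DataFrame`.
#' @export
abundances <- function(x) {
  stopifnot(is(x, "AbundanceTable"))
  assay(x, "abundance")
}

#' @rdname abundances
#' @export
sampleMeta <- function(x) {
  stopifnot(is(x, "AbundanceTable"))
  colData(x)
}

#' @describeIn AbundanceTable-class brief summary with habitat breakdown
#' @param object an `AbundanceTable`
#' @export
setMethod("show", "AbundanceTable", function(object) {
  hab <- table(colData(object)$habitat)
  cat(sprintf("AbundanceTable: %d taxa x %d samples (percent scale)\n",
              nrow(object), ncol(object)))
  cat("  samples per habitat:",
      paste(sprintf("%s=%d", names(hab), hab), collapse = " "), "\n")
})
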