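#' Pairwise ANI structure over a genome set
#'
#' Symmetric average nucleotide identity (percent, unit diagonal at 100)
#' and alignment-fraction matrices over the same genome set, as consumed by
#' [dereplicateGenomes()]. ANI computation itself (fastANI/dRep style) is
#' upstream; this class only validates and carries the result.
#'
#' @slot ani symmetric percent matrix, diagonal 100.
#' @slot alignFrac symmetric fraction matrix in [0, 1].
#' @export
setClass("ANIMatrix",
  representation(ani = "matrix", alignFrac = "matrix"))

setValidity("ANIMatrix", function(object) {
  a <- object@ani; f <- object@alignFrac
  msg <- character()
  if (!identical(dim(a), dim(f)) || nrow(a) != ncol(a))
    return("ani and alignFrac must be square matrices of equal dimension")
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a)))
    msg <- c(msg, "ani must carry matching genome ids as dimnames")
  if (max(abs(a - t(a))) > 1e-9 || max(abs(f - t(f))) > 1e-9)
    msg <- c(msg, "matrices must be symmetric within 1e-9")
  if (any(abs(diag(a) - 100) > 1e-9))
    msg <- c(msg, "ani diagonal must be 100")
  if (any(a < 0 | a > 100)) msg <- c(msg, "ani must lie in [0, 100]")
  if (any(f < 0 | f > 1)) msg <- c(msg, "alignFrac must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an ANIMatrix
#'
#' @param ani symmetric genome-by-genome ANI matrix in percent with genome
#'   ids as dimnames; diagonal 100.
#' @param alignFrac matching alignment-fraction matrix in `[0, 1]`
#'   (diagonal 1). Defaults to full alignment everywhere, for workflows
#'   that only have ANI values.
#' @return An [ANIMatrix-class].
#' @export
ANIMatrix <- function(ani, alignFrac = NULL) {
  ani <- as.matrix(ani)
  if (is.null(alignFrac)) {
    alignFrac <- matrix(1, nrow(ani), ncol(ani), dimnames = dimnames(ani))
  }
  alignFrac <- as.matrix(alignFrac)
  dimnames(alignFrac) <- dimnames(ani)
  new("ANIMatrix", ani = ani, alignFrac = alignFrac)
}

#' Accessors for ANIMatrix
#' @param x an [ANIMatrix-class]
#' @return `aniValues()` the percent ANI matrix; `alignFractions()` the
#'   aligned-fraction matrix; `genomeIds()` the genome identifiers.
#' @export
aniValues <- function(x) {
  stopifnot(is(x, "ANIMatrix"))
  x@ani
}

#' @rdname aniValues
#' @export
alignFractions <- function(x) {
  stopifnot(is(x, "ANIMatrix"))
  x@alignFrac
}

#' @rdname aniValues
#' @export
genomeIds <- function(x) {
  stopifnot(is(x, "ANIMatrix"))
  rownames(x@ani)
}

#' @describeIn ANIMatrix-class dimensions summary
#' @param object an `ANIMatrix`
#' @export
setMethod("show", "ANIMatrix", function(object) {
  n <- nrow(object@ani)
  if (n < 2L) {
    cat(sprintf("ANIMatrix over %d genome(s)\n", n))
  } else {
    cat(sprintf("ANIMatrix over %d genomes (ANI %.1f-%.1f%% off-diagonal)\n",
                n, min(object@ani[upper.tri(object@ani)]),
                max(object@ani[upper.tri(object@ani)])))
  }
})
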