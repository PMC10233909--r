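#' Ordered gene annotation of one genome
#'
#' Holds the genes of a (draft) genome ordered by contig and position, with
#' the annotations that locus detection consumes: CAZyme family labels
#' (dbCAN-style, e.g. `GH16`, `GH5_2`, `PL7`), a functional role flag
#' (`none`, `susC`, `susD`, `tonB`, `sulfatase`) and a signal-peptide flag.
#' All within-genome addressing is by the 0-based `gene_index` in contig
#' order -- locus chaining is gene-count based, not bp based -- while
#' `start`/`end` keep the original 1-based inclusive coordinates.
#'
#' @slot genomeId single genome identifier.
#' @slot genes a [S4Vectors::DataFrame] with columns `gene_id`, `contig_id`,
#'   `gene_index`, `start`, `end`, `strand`, `cazy_families`
#'   (a `CharacterList`), `role`, `signal_peptide`.
#' @export
setClass("GenomeAnnotation",
  representation(genomeId = "character", genes = "DataFrame"))

.FAMILY_RE <- "^(GH|GT|PL|CE|AA|CBM)[0-9]+(_[0-9]+)?$"
.ROLES <- c("none", "susC", "susD", "tonB", "sulfatase")

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  need <- c("gene_id", "contig_id", "gene_index", "start", "end", "strand",
            "cazy_families", "role", "signal_peptide")
  if (!all(need %in% colnames(g)))
    return(paste("genes must have columns:", paste(need, collapse = ", ")))
  if (nrow(g) == 0L) return(TRUE)
  msg <- character()
  if (anyDuplicated(g$gene_id))
    msg <- c(msg, "duplicated gene ids")
  if (!all(g$role %in% .ROLES))
    msg <- c(msg, "invalid role flag")
  fam <- unlist(g$cazy_families)
  if (length(fam) && !all(grepl(.FAMILY_RE, fam)))
    msg <- c(msg, "malformed CAZyme family label")
  if (any(g$start > g$end)) msg <- c(msg, "start must be <= end")
  # 0-based, gap-free, strictly increasing gene_index per contig
  for (ct in unique(g$contig_id)) {
    gi <- g$gene_index[g$contig_id == ct]
    if (!identical(as.integer(gi), seq_along(gi) - 1L)) {
      msg <- c(msg, sprintf("gene_index of contig %s must run 0..n-1", ct))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' Genes are sorted by contig then start coordinate and assigned a 0-based
#' `gene_index` per contig.
#'
#' @param genomeId genome identifier.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, and optionally `strand` (default `"+"`), `cazy_families`
#'   (semicolon-separated string or list of character vectors; empty for
#'   none), `role` (default `"none"`) and `signal_peptide` (0/1 or logical).
#'
#' @return A [GenomeAnnotation-class].
#' @examples
#' g <- data.frame(gene_id = paste0("g", 1:4), contig_id = "c1",
#'                 start = c(1, 1001, 2001, 3001), end = c(900, 1901, 2901, 3901),
#'                 cazy_families = c("", "", "GH16", "GH3"),
#'                 role = c("susC", "susD", "none", "none"))
#' GenomeAnnotation("demo", g)
#' @export
GenomeAnnotation <- function(genomeId, genes) {
  genes <- as.data.frame(genes)
  if (is.null(genes$strand)) genes$strand <- "+"
  if (is.null(genes$role)) genes$role <- "none"
  if (is.null(genes$signal_peptide)) genes$signal_peptide <- FALSE
  if (is.null(genes$cazy_families)) genes$cazy_families <- ""
  o <- order(genes$contig_id, genes$start)
  genes <- genes[o, , drop = FALSE]
  fam <- genes$cazy_families
  if (!is.list(fam)) {
    fam <- strsplit(as.character(fam), ";", fixed = TRUE)
    fam <- lapply(fam, function(f) f[nzchar(f)])
  }
  gi <- unlist(lapply(split(seq_len(nrow(genes)), genes$contig_id)[
    unique(genes$contig_id)], seq_along), use.names = FALSE) - 1L
  # split() groups by contig; reassemble in contig order
  df <- S4Vectors::DataFrame(
    gene_id = as.character(genes$gene_id),
    contig_id = as.character(genes$contig_id),
    gene_index = NA_integer_,
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand),
    cazy_families = IRanges::CharacterList(fam),
    role = as.character(genes$role),
    signal_peptide = as.logical(as.integer(as.logical(genes$signal_peptide)))
  )
  for (ct in unique(df$contig_id)) {
    i <- which(df$contig_id == ct)
    df$gene_index[i] <- seq_along(i) - 1L
  }
  new("GenomeAnnotation", genomeId = as.character(genomeId), genes = df)
}

#' Accessors for GenomeAnnotation
#'
#' @param x a [GenomeAnnotation-class]
#' @return `genomeId()` the identifier; `genes()` the per-gene `DataFrame`.
#' @export
genomeId <- function(x) {
  stopifnot(is(x, "GenomeAnnotation"))
  x@genomeId
}

#' @rdname genomeId
#' @export
genes <- function(x) {
  stopifnot(is(x, "GenomeAnnotation"))
  x@genes
}

#' @describeIn GenomeAnnotation-class summary of contigs and annotations
#' @param object a `GenomeAnnotation`
#' @export
setMethod("show", "GenomeAnnotation", function(object) {
  g <- object@genes
  ncaz <- sum(lengths(g$cazy_families) > 0)
  cat(sprintf("GenomeAnnotation %s: %d genes on %d contig(s); %d CAZyme, %d susC, %d susD, %d tonB, %d sulfatase\n",
              object@genomeId, nrow(g), length(unique(g$contig_id)), ncaz,
              sum(g$role == "susC"), sum(g$role == "susD"),
              sum(g$role == "tonB"), sum(g$role == "sulfatase")))
})
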