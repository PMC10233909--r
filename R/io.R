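#' Read a relative-abundance table with sample metadata
#'
#' Reads a wide TSV (first column taxon id, remaining columns sample ids,
#' values relative abundances in percent) together with a metadata TSV
#' mapping sample ids to habitat/season codes. Missing cells become 0.
#'
#' @param path abundance TSV.
#' @param meta_path metadata TSV with columns `sample_id`, `habitat`,
#'   `season` and optionally `replicate`.
#' @param flag_col optional name of a non-numeric annotation column in the
#'   abundance TSV (e.g. a core/dominant flag); it is moved into `rowData`
#'   instead of being parsed as a sample.
#'
#' @return An [AbundanceTable-class].
#' @details A sample column without a metadata row is a hard error naming
#'   the orphan sample(s); negative abundances are a hard error.
#' @export
readAbundanceTable <- function(path, meta_path, flag_col = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("abundance table needs a taxon column and >= 1 sample")
  taxa <- as.character(tab[[1L]])
  tab <- tab[, -1L, drop = FALSE]
  rd <- NULL
  if (!is.null(flag_col)) {
    if (!flag_col %in% colnames(tab))
      stop("flag column '", flag_col, "' not found")
    rd <- data.frame(flag = tab[[flag_col]])
    names(rd) <- flag_col
    tab <- tab[, setdiff(colnames(tab), flag_col), drop = FALSE]
  }
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "habitat", "season") %in% colnames(meta)))
    stop("metadata must have columns sample_id, habitat, season")
  orphans <- setdiff(colnames(tab), meta$sample_id)
  if (length(orphans))
    stop("sample(s) without metadata: ", paste(orphans, collapse = ", "))
  v <- as.matrix(data.matrix(tab))
  v[is.na(v)] <- 0
  if (any(v < 0)) stop("negative abundance values are not allowed")
  rownames(v) <- taxa
  AbundanceTable(v, meta, rowData = rd)
}

.parseGeneFrame <- function(df, where) {
  need <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand",
            "cazy_families", "role", "signal_peptide")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing column(s) in ", where, ": ", paste(miss, collapse = ", "))
  fams <- strsplit(as.character(df$cazy_families), ";", fixed = TRUE)
  fams <- lapply(fams, function(f) f[nzchar(f) & !is.na(f)])
  bad <- which(vapply(fams, function(f) any(!grepl(.FAMILY_RE, f)), logical(1)))
  if (length(bad))
    stop(sprintf("malformed CAZyme family label at %s line %d: '%s'",
                 where, bad[1L] + 1L,
                 paste(fams[[bad[1L]]], collapse = ";")))
  df$cazy_families <- fams
  out <- list()
  for (gid in unique(df$genome_id)) {
    sub <- df[df$genome_id == gid, , drop = FALSE]
    dup <- unique(sub$gene_id[duplicated(sub$gene_id)])
    if (length(dup))
      stop("duplicated gene id(s) in genome ", gid, ": ",
           paste(dup, collapse = ", "))
    out[[gid]] <- GenomeAnnotation(gid, sub)
  }
  out
}

#' Read per-genome gene annotation tables
#'
#' Normalization layer over dbCAN/HMM-style annotation output. The TSV
#' dialect has columns `genome_id`, `contig_id`, `gene_id`, `start`, `end`,
#' `strand`, `cazy_families` (semicolon-separated, may be empty), `role`
#' (`none`/`susC`/`susD`/`tonB`/`sulfatase`) and `signal_peptide` (0/1).
#' The GFF3 dialect carries the same fields as attribute keys, one feature
#' per gene; coordinates are 1-based inclusive in both dialects.
#'
#' Family labels are validated against `^(GH|GT|PL|CE|AA|CBM)[0-9]+(_[0-9]+)?$`
#' (subfamily labels such as `GH5_2` are accepted); a malformed label is a
#' hard error reporting the offending line.
#'
#' @param path input file.
#' @param dialect `"tsv"` (default) or `"gff3"`.
#' @return A named list of [GenomeAnnotation-class], one per `genome_id`.
#' @export
readGeneTable <- function(path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    return(.parseGeneFrame(df, basename(path)))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr))
  df <- data.frame(
    genome_id = as.character(mc$genome_id),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(mc$gene_id),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    cazy_families = if (is.null(mc$cazy_families)) "" else
      as.character(mc$cazy_families),
    role = if (is.null(mc$role)) "none" else as.character(mc$role),
    signal_peptide = if (is.null(mc$signal_peptide)) 0L else
      as.integer(mc$signal_peptide),
    stringsAsFactors = FALSE)
  df$cazy_families[is.na(df$cazy_families)] <- ""
  df$role[is.na(df$role)] <- "none"
  df$signal_peptide[is.na(df$signal_peptide)] <- 0L
  .parseGeneFrame(df, basename(path))
}

#' Write / re-read a locus report
#'
#' `writeLocusReport()` serializes a [LocusSet-class] to a TSV with one row
#' per locus (genome, contig, span, category, architecture, composition
#' counts, CAZyme density, family string and inferred substrates) in
#' deterministic order (genome, contig, first gene index).
#' `readLocusReport()` restores a `LocusSet` from such a file;
#' `cazyme_density` is recomputed from the counts so the round trip is
#' exact.
#'
#' @param x a [LocusSet-class].
#' @param path output (input) TSV path.
#' @return `writeLocusReport()` returns `path` invisibly;
#'   `readLocusReport()` a `LocusSet`.
#' @export
writeLocusReport <- function(x, path) {
  stopifnot(is(x, "LocusSet"))
  l <- x@loci
  o <- order(l$genome_id, l$contig_id, l$first_index)
  l <- l[o, , drop = FALSE]
  df <- data.frame(
    genome_id = l$genome_id, contig_id = l$contig_id,
    category = l$category, architecture = l$architecture,
    first_index = l$first_index, last_index = l$last_index,
    n_genes = l$n_genes, n_cazymes = l$n_cazymes,
    n_susCD_pairs = l$n_susCD_pairs, n_sulfatases = l$n_sulfatases,
    cazyme_density = l$cazyme_density,
    cazy_string = vapply(l$cazy_string, paste, "", collapse = ";"),
    gene_ids = vapply(l$gene_ids, paste, "", collapse = ";"),
    substrates = vapply(l$substrates, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLocusReport
#' @export
readLocusReport <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(cazy_string = "character",
                                  gene_ids = "character",
                                  substrates = "character"))
  if (nrow(df) == 0L) return(LocusSet())
  df$cazyme_density <- df$n_cazymes / df$n_genes
  LocusSet(df)
}

#' Read a long-format ANI table
#'
#' Builds an [ANIMatrix-class] from a TSV with columns `g1`, `g2`, `ani`
#' and optionally `af` (aligned fraction). Pairs may be given in one
#' direction only; the matrix is symmetrized and the diagonal fixed at
#' 100 (alignment fraction 1). Missing pairs default to ANI 0.
#'
#' @param path TSV path.
#' @return An [ANIMatrix-class].
#' @export
readANITable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("g1", "g2", "ani") %in% colnames(df)))
    stop("ANI table must have columns g1, g2, ani")
  ids <- sort(unique(c(df$g1, df$g2)))
  n <- length(ids)
  ani <- matrix(0, n, n, dimnames = list(ids, ids))
  af <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(df$g1, ids); j <- match(df$g2, ids)
  ani[cbind(i, j)] <- df$ani
  ani[cbind(j, i)] <- df$ani
  afv <- if ("af" %in% colnames(df)) df$af else rep(1, nrow(df))
  af[cbind(i, j)] <- afv
  af[cbind(j, i)] <- afv
  diag(ani) <- 100
  diag(af) <- 1
  ANIMatrix(ani, af)
}
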