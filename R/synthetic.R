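#' Simulate a relative-abundance table with planted category truth
#'
#' Generates a taxa-by-sample percent abundance table over the four
#' macroalgal habitats in which `n_core` taxa qualify (prevalence and
#' abundance thresholds of `cfg`) in every habitat, `n_dominant` in
#' exactly three, `n_specific` in one or two, and `n_background` in none.
#' Columns are renormalized to sum to 100 whenever the planted community
#' mass supports it; sparse plantings are left as partial-community
#' columns (the table invariant is a sum of at most 100) so background
#' taxa are not inflated past the abundance threshold. The planted truth
#' is enforced post hoc: any sample violating the planted qualification
#' pattern is resampled, so recovery by [classifyTaxa()] is exact rather
#' than merely expected. Samples cycle through the four seasons.
#'
#' @param n_core,n_dominant,n_specific,n_background taxon counts per
#'   planted category (defaults 14/14/8/30, the survey's core/dominant
#'   design).
#' @param samples_per_habitat samples per habitat (default 12; four
#'   seasons x three replicates).
#' @param habitats macroalgal habitat codes; all four are required
#'   whenever core or dominant taxa are planted.
#' @param core_abundance_mean mean percent abundance (before column
#'   renormalization) of a qualifying taxon in a qualifying habitat
#'   (default 3).
#' @param noise_sd abundance noise s.d. in percent (default 1.5).
#' @param dropout_prob probability that a qualifying taxon is absent from
#'   any given sample; must stay below `1 - prevalenceMin` so the planted
#'   prevalence is feasible (enforced, default 0.05).
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @param cfg a [PhycoConfig-class] defining the qualification thresholds
#'   the truth is enforced against.
#' @return A list: `table` (an [AbundanceTable-class]) and `truth`
#'   (data.frame `taxon`, `category`).
#' @export
simCommunity <- function(n_core = 14L, n_dominant = 14L, n_specific = 8L,
                         n_background = 30L, samples_per_habitat = 12L,
                         habitats = c("H", "R", "L", "B"),
                         core_abundance_mean = 3, noise_sd = 1.5,
                         dropout_prob = 0.05, seed = 1L,
                         cfg = phycoConfig()) {
  if (dropout_prob >= 1 - cfg@prevalenceMin)
    stop("dropout_prob must be < 1 - prevalenceMin to keep planted core taxa")
  if (core_abundance_mean * n_core > 100)
    stop("infeasible spec: core_abundance_mean x n_core exceeds 100%")
  if ((n_core > 0L || n_dominant > 0L) &&
      !setequal(habitats, .MACROALGAL))
    stop("core/dominant planting requires all four macroalgal habitats")
  habitats <- intersect(.MACROALGAL, habitats)
  nh <- length(habitats)
  set.seed(seed)
  taxa <- c(if (n_core) paste0("core_", seq_len(n_core)),
            if (n_dominant) paste0("dominant_", seq_len(n_dominant)),
            if (n_specific) paste0("specific_", seq_len(n_specific)),
            if (n_background) paste0("background_", seq_len(n_background)))
  nt <- length(taxa)
  if (nt == 0L) stop("no taxa requested")

  # planted qualification pattern: taxa x habitats
  Q <- matrix(FALSE, nt, nh, dimnames = list(taxa, habitats))
  if (n_core) Q[seq_len(n_core), ] <- TRUE
  drop3 <- utils::combn(nh, nh - 1L)  # all 3-of-4 habitat subsets
  for (i in seq_len(n_dominant))
    Q[n_core + i, drop3[, (i - 1L) %% ncol(drop3) + 1L]] <- TRUE
  for (i in seq_len(n_specific)) {
    k <- 1L + (i %% 2L)  # alternate 1 and 2 qualifying habitats
    Q[n_core + n_dominant + i,
      ((i - 1L + seq_len(k) - 1L) %% nh) + 1L] <- TRUE
  }

  nS <- samples_per_habitat
  max_drop <- floor((1 - cfg@prevalenceMin) * nS)
  values <- NULL
  meta <- NULL
  for (h in habitats) {
    qh <- Q[, h]
    # predetermine the guaranteed >=1% "peak" sample and the dropout
    # pattern per qualifying taxon, truncated to keep prevalence feasible
    peak <- sample.int(nS, nt, replace = TRUE)
    dropout <- matrix(FALSE, nt, nS)
    for (t in which(qh)) {
      cand <- setdiff(seq_len(nS), peak[t])
      k <- min(rbinom(1L, length(cand), dropout_prob), max_drop)
      if (k > 0L) dropout[t, sample(cand, k)] <- TRUE
    }
    hv <- matrix(0, nt, nS)
    for (s in seq_len(nS)) {
      for (try in seq_len(1000L)) {
        raw <- numeric(nt)
        q <- which(qh)
        raw[q] <- pmin(pmax(abs(rnorm(length(q), core_abundance_mean,
                                      noise_sd)), 0.2), 20)
        raw[q][dropout[q, s]] <- 0
        pk <- q[peak[q] == s & !dropout[q, s]]
        raw[pk] <- pmax(raw[pk], 3 * cfg@abundanceMin)
        nq <- which(!qh)
        on <- runif(length(nq)) < 0.5
        raw[nq[on]] <- runif(sum(on), 0.01, 0.4)
        # renormalize to a full community (sum 100) when the planted mass
        # supports it; sparse plantings stay as partial-community columns
        # (the table invariant is sum <= 100) so background taxa are not
        # inflated past the abundance threshold
        tot <- sum(raw)
        col <- if (tot > 0 && 100 / tot <= 2) 100 * raw / tot else raw
        # post-hoc guards: non-qualifiers stay < abundanceMin, the peak
        # sample certifies the >=1% condition
        if (all(col[nq] < cfg@abundanceMin) &&
            all(col[q[peak[q] == s & !dropout[q, s]]] >= cfg@abundanceMin))
          break
        if (try == 1000L) stop("infeasible spec: could not satisfy planted truth")
      }
      hv[, s] <- col
    }
    sid <- sprintf("%s%d_%d", h, rep(1:4, length.out = nS), seq_len(nS))
    colnames(hv) <- sid
    values <- cbind(values, hv)
    meta <- rbind(meta, data.frame(
      sample_id = sid, habitat = h,
      season = rep(1:4, length.out = nS),
      replicate = seq_len(nS), stringsAsFactors = FALSE))
  }
  rownames(values) <- taxa
  nquals <- rowSums(Q)
  truth <- data.frame(
    taxon = taxa,
    category = ifelse(nquals == 4L, "core",
               ifelse(nquals == 3L, "dominant",
               ifelse(nquals >= 1L, "host_specific", "background"))),
    stringsAsFactors = FALSE)
  list(table = AbundanceTable(values, meta), truth = truth)
}

.buildLocusGenes <- function(category, architecture, cazy_families,
                             n_sulfatases, spacer_genes, window) {
  if (spacer_genes >= window)
    stop("spacer_genes must be < windowGenes to keep the planted locus intact")
  arch_block <- switch(architecture,
    single = c("susC", "susD"),
    tandem_repeat = c("susC", "susD", "susC", "susD"),
    hybrid = c("susC", "susD"),
    tandem_repeat_hybrid = c("susC", "susD", "susC", "susD"),
    none = character(0),
    stop("unknown architecture: ", architecture))
  markers <- switch(category,
    PUL = c(arch_block, cazy_families),
    PUL_like = c("tonB", cazy_families),
    CGC = cazy_families,
    susCD_only = arch_block,
    stop("unknown category: ", category))
  if (category %in% c("PUL", "susCD_only") &&
      architecture %in% c("hybrid", "tandem_repeat_hybrid"))
    markers <- c(markers, "susC")  # trailing unpaired receptor
  if (n_sulfatases > 0L)
    markers <- c(markers, rep("sulfatase", n_sulfatases))
  is_role <- markers %in% c("susC", "susD", "tonB", "sulfatase")
  out <- list()
  npairs_seen <- 0L
  for (i in seq_along(markers)) {
    role <- if (is_role[i]) markers[i] else "none"
    fam <- if (is_role[i]) character(0) else markers[i]
    out[[length(out) + 1L]] <- list(role = role, fam = fam)
    # spacers between markers, but never inside a susCD pair or between
    # tandem pairs (adjacency is what the architecture encodes)
    if (i < length(markers)) {
      inside_pair <- is_role[i] && markers[i] == "susC" &&
        is_role[i + 1L] && markers[i + 1L] == "susD"
      tandem_join <- architecture %in%
        c("tandem_repeat", "tandem_repeat_hybrid") &&
        is_role[i] && markers[i] == "susD" &&
        is_role[i + 1L] && markers[i + 1L] == "susC" && npairs_seen == 0L
      if (is_role[i] && markers[i] == "susD") npairs_seen <- npairs_seen + 1L
      if (!inside_pair && !tandem_join && spacer_genes > 0L) {
        for (j in seq_len(spacer_genes))
          out[[length(out) + 1L]] <- list(role = "none", fam = character(0))
      }
    }
  }
  out
}

#' Simulate an annotated genome with planted loci
#'
#' Builds a [GenomeAnnotation-class] in which the requested loci appear
#' verbatim at recorded gene indices, padded by at least `windowGenes`
#' non-marker genes so planted loci can never merge with each other or
#' with background CAZymes. Background CAZyme genes are sprinkled at
#' `background_cazyme_rate` on positions at least `windowGenes` away from
#' any planted marker and from each other.
#'
#' @param n_contigs,genes_per_contig genome shape (defaults 2 x 120).
#' @param planted_loci list of locus specs; each a list with `category`
#'   (`PUL`, `PUL_like`, `CGC`, `susCD_only`), `architecture` (`single`,
#'   `tandem_repeat`, `hybrid`, `tandem_repeat_hybrid`, `none`),
#'   `cazy_families` (character vector, in gene order), `n_sulfatases`
#'   (default 0) and `spacer_genes` (non-marker genes inserted between
#'   locus markers, must be `< windowGenes`; default 0).
#' @param background_cazyme_rate per-gene probability of an isolated
#'   background CAZyme (default 0.01).
#' @param seed integer seed.
#' @param genome_id identifier for the genome.
#' @param cfg a [PhycoConfig-class].
#' @return A list: `annotation` (a [GenomeAnnotation-class]) and `truth`
#'   (data.frame `contig_id`, `first_index`, `last_index`, `category`,
#'   `architecture`).
#' @export
simAnnotatedGenome <- function(n_contigs = 2L, genes_per_contig = 120L,
                               planted_loci = list(),
                               background_cazyme_rate = 0.01,
                               seed = 1L, genome_id = "synth_genome",
                               cfg = phycoConfig()) {
  set.seed(seed)
  window <- cfg@windowGenes
  bg_fams <- c("GH2", "GH13", "GH16", "GH29", "PL7", "CE1", "CBM32", "AA3")
  contigs <- lapply(seq_len(n_contigs), function(i)
    replicate(genes_per_contig, list(role = "none", fam = character(0)),
              simplify = FALSE))
  truth <- list()
  marker_pos <- lapply(seq_len(n_contigs), function(i) integer(0))
  cursor <- rep(window + 1L, n_contigs)  # leave a leading pad
  ci <- 1L
  for (pl in planted_loci) {
    if (is.null(pl$n_sulfatases)) pl$n_sulfatases <- 0L
    if (is.null(pl$spacer_genes)) pl$spacer_genes <- 0L
    if (is.null(pl$architecture)) pl$architecture <- "none"
    lg <- .buildLocusGenes(pl$category, pl$architecture,
                           pl$cazy_families, pl$n_sulfatases,
                           pl$spacer_genes, window)
    placed <- FALSE
    for (k in seq_len(n_contigs)) {
      cand <- ((ci - 1L + k - 1L) %% n_contigs) + 1L
      if (cursor[cand] + length(lg) + window <= genes_per_contig) {
        at <- cursor[cand]
        for (j in seq_along(lg)) contigs[[cand]][[at + j - 1L]] <- lg[[j]]
        mk <- at + which(vapply(lg, function(g)
          g$role != "none" || length(g$fam) > 0, logical(1))) - 1L
        truth[[length(truth) + 1L]] <- data.frame(
          contig_id = sprintf("contig_%d", cand),
          first_index = min(mk) - 1L, last_index = max(mk) - 1L,
          category = pl$category, architecture = pl$architecture,
          stringsAsFactors = FALSE)
        marker_pos[[cand]] <- c(marker_pos[[cand]], mk)
        cursor[cand] <- at + length(lg) + window
        ci <- cand + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("contig too short for requested loci (",
           genes_per_contig, " genes per contig)")
  }
  # isolated background CAZymes, >= window genes from loci and each other
  for (k in seq_len(n_contigs)) {
    occupied <- marker_pos[[k]]
    elig <- setdiff(seq_len(genes_per_contig), unlist(lapply(
      occupied, function(p) seq(max(1L, p - window), min(genes_per_contig,
                                                         p + window)))))
    elig <- elig[runif(length(elig)) < background_cazyme_rate]
    kept <- integer(0)
    for (p in sort(elig)) {
      if (!length(kept) || p - kept[length(kept)] > window) kept <- c(kept, p)
    }
    for (p in kept)
      contigs[[k]][[p]] <- list(role = "none",
                                fam = sample(bg_fams, 1L))
  }
  gene_rows <- do.call(rbind, lapply(seq_len(n_contigs), function(k) {
    n <- length(contigs[[k]])
    data.frame(
      gene_id = sprintf("%s_c%d_g%04d", genome_id, k, seq_len(n)),
      contig_id = sprintf("contig_%d", k),
      start = (seq_len(n) - 1L) * 1000L + 1L,
      end = (seq_len(n) - 1L) * 1000L + 900L,
      strand = "+",
      cazy_families = vapply(contigs[[k]], function(g)
        paste(g$fam, collapse = ";"), ""),
      role = vapply(contigs[[k]], `[[`, "", "role"),
      signal_peptide = 0L,
      stringsAsFactors = FALSE)
  }))
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(contig_id = character(), first_index = integer(),
                           last_index = integer(), category = character(),
                           architecture = character())
  list(annotation = GenomeAnnotation(genome_id, gene_rows), truth = truth)
}

#' Simulate a block-structured ANI matrix with planted species
#'
#' Within-species ANI is drawn from U(96, 100) with aligned fraction in
#' [0.7, 0.95]; between-species ANI from U(75, 93) with aligned fraction
#' in [0.3, 0.6]. The matrix is symmetric with a unit diagonal (100% /
#' 1.0), so default-threshold dereplication (95% ANI, AF 0.65) recovers
#' the planted species exactly.
#'
#' @param n_species number of species blocks (>= 1).
#' @param genomes_per_species genomes per species.
#' @param seed integer seed.
#' @return A list: `ani` (an [ANIMatrix-class]) and `truth` (data.frame
#'   `genome_id`, `species`).
#' @export
simANIMatrix <- function(n_species = 3L, genomes_per_species = 2L,
                         seed = 1L) {
  stopifnot(n_species >= 1L, genomes_per_species >= 1L)
  set.seed(seed)
  ids <- unlist(lapply(seq_len(n_species), function(s)
    sprintf("sp%02d_g%02d", s, seq_len(genomes_per_species))))
  sp <- rep(seq_len(n_species), each = genomes_per_species)
  n <- length(ids)
  ani <- matrix(0, n, n, dimnames = list(ids, ids))
  af <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      same <- sp[i] == sp[j]
      ani[i, j] <- ani[j, i] <- if (same) runif(1, 96, 100)
                                else runif(1, 75, 93)
      af[i, j] <- af[j, i] <- if (same) runif(1, 0.7, 0.95)
                              else runif(1, 0.3, 0.6)
    }
  }
  diag(ani) <- 100
  diag(af) <- 1
  list(ani = ANIMatrix(ani, af),
       truth = data.frame(genome_id = ids, species = sp,
                          stringsAsFactors = FALSE))
}

#' Simulate a strain-by-ASV 16S identity matrix with planted matches
#'
#' A `matched_fraction` of strains is paired to a random ASV at identity
#' drawn from U(98.7, 100); every unmatched (strain, ASV) combination is
#' drawn below `cultivabilityIdentity - 1` (i.e. U(85, 96)), so matching
#' and cultivability recover the planted pairs exactly at the default
#' thresholds.
#'
#' @param n_strains,n_asvs matrix dimensions.
#' @param matched_fraction fraction of strains given a planted ASV match.
#' @param seed integer seed.
#' @param cfg a [PhycoConfig-class].
#' @return A list: `identity` (strains x ASVs percent matrix) and `truth`
#'   (data.frame `strain`, `asv` of planted pairs).
#' @export
simIdentityMatrix <- function(n_strains = 20L, n_asvs = 15L,
                              matched_fraction = 0.5, seed = 1L,
                              cfg = phycoConfig()) {
  stopifnot(matched_fraction >= 0, matched_fraction <= 1)
  set.seed(seed)
  strains <- sprintf("strain%03d", seq_len(n_strains))
  asvs <- sprintf("asv%03d", seq_len(n_asvs))
  upper <- cfg@cultivabilityIdentity - 1
  m <- matrix(runif(n_strains * n_asvs, 85, upper),
              n_strains, n_asvs, dimnames = list(strains, asvs))
  n_match <- round(matched_fraction * n_strains)
  truth <- data.frame(strain = character(), asv = character(),
                      stringsAsFactors = FALSE)
  if (n_match > 0L && n_asvs > 0L) {
    sel <- sample.int(n_strains, n_match)
    tgt <- sample.int(n_asvs, n_match, replace = TRUE)
    m[cbind(sel, tgt)] <- runif(n_match, cfg@speciesIdentity16S, 100)
    truth <- data.frame(strain = strains[sel], asv = asvs[tgt],
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$strain), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(identity = m, truth = truth)
}
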