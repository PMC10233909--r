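#' Pipeline configuration
#'
#' A single object holding every numeric threshold used across the pipeline,
#' so that analyses are reproducible from one configuration record. Defaults
#' are the study conditions of a multi-habitat phycosphere survey: a genus
#' qualifies in a habitat when present in >= 85% of its samples with >= 1%
#' relative abundance in at least one sample; loci are chained with a
#' ten-gene sliding window; 16S species/genus thresholds are 98.7%/94.5%
#' with cultivability matching at 97%; genomes are dereplicated at 95% ANI
#' over >= 65% aligned fraction, with 99% ANI non-redundancy.
#'
#' @slot prevalenceMin fraction of a habitat's samples a taxon must be
#'   present in to qualify (default 0.85).
#' @slot abundanceMin relative abundance in percent that must be reached in
#'   at least one sample of the habitat (default 1.0).
#' @slot presenceFloor abundance (percent) strictly above which a taxon
#'   counts as present; default 0, i.e. any non-zero abundance.
#' @slot abundanceScope `"habitat"` (default) evaluates the abundanceMin
#'   condition within each habitat; `"global"` lets a single high-abundance
#'   sample anywhere qualify the taxon everywhere it is prevalent.
#' @slot windowGenes sliding-window width in genes for locus chaining
#'   (default 10): two marker genes join one locus when separated by fewer
#'   than `windowGenes` intervening genes.
#' @slot cgcMinCazymes minimum CAZyme genes for a receptor-free cluster to
#'   count as CAZyme-rich (default 3).
#' @slot markerClasses CAZyme classes that seed and extend loci; default the
#'   catabolic classes GH, PL, CE, AA, CBM (GT excluded).
#' @slot pairOrientation `"CD"` (default) requires susC immediately followed
#'   by susD in gene order to form a pair; `"both"` also accepts susD-susC.
#' @slot strandAware reserved flag; strand is stored but ignored by
#'   detection when `FALSE` (default).
#' @slot speciesIdentity16S,genusIdentity16S,cultivabilityIdentity 16S rRNA
#'   identity thresholds in percent (defaults 98.7, 94.5, 97).
#' @slot aniSpecies,aniAlignmentMin,aniRedundancy ANI species threshold
#'   (percent, default 95), minimum aligned fraction (default 0.65) and
#'   within-species redundancy ANI (default 99).
#' @slot qualityCutoffs named list of genome quality cutoffs; see
#'   [assignQualityTier()].
#' @slot pulClusterDistanceCut distance cut for PUL clustering; the default
#'   0 groups only compositionally identical PULs.
#' @slot randomSeed integer seed recorded for provenance.
#'
#' @seealso [phycoConfig()]
#' @export
setClass("PhycoConfig",
  representation(
    prevalenceMin = "numeric",
    abundanceMin = "numeric",
    presenceFloor = "numeric",
    abundanceScope = "character",
    windowGenes = "integer",
    cgcMinCazymes = "integer",
    markerClasses = "character",
    pairOrientation = "character",
    strandAware = "logical",
    speciesIdentity16S = "numeric",
    genusIdentity16S = "numeric",
    cultivabilityIdentity = "numeric",
    aniSpecies = "numeric",
    aniAlignmentMin = "numeric",
    aniRedundancy = "numeric",
    qualityCutoffs = "list",
    pulClusterDistanceCut = "numeric",
    randomSeed = "integer"
  )
)

.CAZY_CLASSES <- c("GH", "GT", "PL", "CE", "AA", "CBM")
.HABITATS <- c("H", "R", "L", "B", "S", "N")
.MACROALGAL <- c("H", "R", "L", "B")

setValidity("PhycoConfig", function(object) {
  msg <- character()
  pct <- c(
    abundanceMin = object@abundanceMin,
    speciesIdentity16S = object@speciesIdentity16S,
    genusIdentity16S = object@genusIdentity16S,
    cultivabilityIdentity = object@cultivabilityIdentity,
    aniSpecies = object@aniSpecies,
    aniRedundancy = object@aniRedundancy
  )
  if (any(pct < 0 | pct > 100))
    msg <- c(msg, "percent thresholds must lie in [0, 100]")
  frac <- c(object@prevalenceMin, object@aniAlignmentMin)
  if (any(frac < 0 | frac > 1))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@windowGenes < 1L)
    msg <- c(msg, "windowGenes must be >= 1")
  if (object@cgcMinCazymes < 1L)
    msg <- c(msg, "cgcMinCazymes must be >= 1")
  if (!all(object@markerClasses %in% .CAZY_CLASSES))
    msg <- c(msg, "markerClasses must be CAZyme classes")
  if (!object@abundanceScope %in% c("habitat", "global"))
    msg <- c(msg, "abundanceScope must be 'habitat' or 'global'")
  if (!object@pairOrientation %in% c("CD", "both"))
    msg <- c(msg, "pairOrientation must be 'CD' or 'both'")
  if (object@pulClusterDistanceCut < 0 || object@pulClusterDistanceCut > 1)
    msg <- c(msg, "pulClusterDistanceCut must lie in [0, 1]")
  qc <- object@qualityCutoffs
  need <- c("high_completeness", "high_contamination", "high_min_trna",
            "nearly_completeness", "nearly_contamination",
            "medium_completeness", "medium_contamination")
  if (!all(need %in% names(qc)))
    msg <- c(msg, paste("qualityCutoffs must contain:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param prevalenceMin,abundanceMin,presenceFloor,abundanceScope community
#'   qualification parameters; see [PhycoConfig-class].
#' @param windowGenes,cgcMinCazymes,markerClasses,pairOrientation,strandAware
#'   locus detection parameters.
#' @param speciesIdentity16S,genusIdentity16S,cultivabilityIdentity 16S
#'   identity thresholds in percent.
#' @param aniSpecies,aniAlignmentMin,aniRedundancy genome dereplication
#'   thresholds.
#' @param qualityCutoffs named list of quality-tier cutoffs; the default
#'   encodes MIMAG high quality (completeness >= 90, contamination < 5,
#'   complete rRNA operon, >= 18 tRNAs), the "nearly complete" tier
#'   (completeness > 90, contamination < 5) and the retention floor
#'   (completeness >= 50, contamination < 10).
#' @param pulClusterDistanceCut distance cut for PUL clustering (default 0).
#' @param randomSeed integer seed recorded with the configuration.
#'
#' @return A validated [PhycoConfig-class] object.
#' @examples
#' cfg <- phycoConfig()
#' cfg@windowGenes
#' @export
phycoConfig <- function(prevalenceMin = 0.85,
                        abundanceMin = 1.0,
                        presenceFloor = 0,
                        abundanceScope = "habitat",
                        windowGenes = 10L,
                        cgcMinCazymes = 3L,
                        markerClasses = c("GH", "PL", "CE", "AA", "CBM"),
                        pairOrientation = "CD",
                        strandAware = FALSE,
                        speciesIdentity16S = 98.7,
                        genusIdentity16S = 94.5,
                        cultivabilityIdentity = 97.0,
                        aniSpecies = 95.0,
                        aniAlignmentMin = 0.65,
                        aniRedundancy = 99.0,
                        qualityCutoffs = list(
                          high_completeness = 90,
                          high_contamination = 5,
                          high_min_trna = 18L,
                          nearly_completeness = 90,
                          nearly_contamination = 5,
                          medium_completeness = 50,
                          medium_contamination = 10
                        ),
                        pulClusterDistanceCut = 0,
                        randomSeed = 1L) {
  new("PhycoConfig",
      prevalenceMin = prevalenceMin,
      abundanceMin = abundanceMin,
      presenceFloor = presenceFloor,
      abundanceScope = abundanceScope,
      windowGenes = as.integer(windowGenes),
      cgcMinCazymes = as.integer(cgcMinCazymes),
      markerClasses = markerClasses,
      pairOrientation = pairOrientation,
      strandAware = strandAware,
      speciesIdentity16S = speciesIdentity16S,
      genusIdentity16S = genusIdentity16S,
      cultivabilityIdentity = cultivabilityIdentity,
      aniSpecies = aniSpecies,
      aniAlignmentMin = aniAlignmentMin,
      aniRedundancy = aniRedundancy,
      qualityCutoffs = qualityCutoffs,
      pulClusterDistanceCut = pulClusterDistanceCut,
      randomSeed = as.integer(randomSeed))
}

#' @describeIn PhycoConfig-class compact threshold listing
#' @param object a `PhycoConfig`
#' @export
setMethod("show", "PhycoConfig", function(object) {
  cat("PhycoConfig\n")
  cat(sprintf("  community: prevalence >= %.2f, abundance >= %.1f%% (scope: %s)\n",
              object@prevalenceMin, object@abundanceMin, object@abundanceScope))
  cat(sprintf("  loci: window %d genes, CGC >= %d CAZymes, markers %s\n",
              object@windowGenes, object@cgcMinCazymes,
              paste(object@markerClasses, collapse = "/")))
  cat(sprintf("  16S: species %.1f%%, genus %.1f%%, cultivability %.1f%%\n",
              object@speciesIdentity16S, object@genusIdentity16S,
              object@cultivabilityIdentity))
  cat(sprintf("  ANI: species %.1f%% (AF >= %.2f), redundancy %.1f%%\n",
              object@aniSpecies, object@aniAlignmentMin, object@aniRedundancy))
})
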