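#' @importFrom rtracklayer import export
#' @importFrom jsonlite toJSON fromJSON write_json read_json
#' @importFrom yaml write_yaml read_yaml
NULL

.simConfigToList <- function(config) {
  sn <- slotNames("SimConfig")
  out <- lapply(sn, function(s) {
    v <- slot(config, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  names(out) <- sn
  out
}

#' Read a simulation config from YAML
#'
#' @param path YAML file with \code{SimConfig} fields (named rate vectors
#'   as mappings with \code{high}/\code{low} keys).
#' @return a \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(path) {
  lst <- read_yaml(path)
  for (s in c("plantedGainRate", "plantedLossRate"))
    if (!is.null(lst[[s]])) lst[[s]] <- unlist(lst[[s]])
  do.call(SimConfig, lst)
}

#' Write a simulation config to YAML
#'
#' @param config a \linkS4class{SimConfig}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSimConfig <- function(config, path) {
  write_yaml(.simConfigToList(config), path, precision = 15L)
  invisible(path)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the cohort as the pipeline's on-disk input bundle: genome FASTA,
#' gene-model TSV, one BED6 file of reads per sample, probe manifest TSV
#' (1-based positions), intensity TSV, pairing TSV, peak BED, bivalent
#' gene list TSV, a JSON truth sidecar (including per-sample mapped
#' totals) and the generating config as YAML.
#'
#' @param cohort an \linkS4class{HmcCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeXStringSet(genomeSeq(cohort), file.path(dir, "genome.fa"))
  g <- geneModels(cohort)
  write.table(data.frame(gene_id = g$gene_id,
                         chrom = as.character(seqnames(g)),
                         start = start(g), end = end(g),
                         strand = as.character(strand(g)),
                         tss = g$tss, tts = g$tts),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (id in names(readSets(cohort))) {
    rs <- readSets(cohort)[[id]]
    gr <- readIntervals(rs)
    mcols(gr) <- NULL
    gr$name <- rep(".", length(gr))
    gr$score <- rep(0L, length(gr))
    export(gr, file.path(dir, paste0("reads_", id, ".bed")),
           format = "BED")
  }
  p <- probeManifest(cohort)
  write.table(data.frame(probe_id = p$probe_id,
                         chrom = as.character(seqnames(p)),
                         pos_1based = start(p),
                         design_type = p$design_type,
                         cross_reactive = p$cross_reactive, snp = p$snp,
                         sex_chrom = p$sex_chrom,
                         true_gene = p$true_gene),
              file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(intensityTable(cohort), file.path(dir, "intensities.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(samplePairing(cohort), file.path(dir, "pairing.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pk <- peakSet(cohort)
  if (length(pk)) {
    pk2 <- pk; mcols(pk2) <- NULL
    export(pk2, file.path(dir, "peaks.bed"), format = "BED")
  } else {
    file.create(file.path(dir, "peaks.bed"))
  }
  write.table(data.frame(gene_id = bivalentGenes(cohort)),
              file.path(dir, "bivalent.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- cohortTruth(cohort)
  ## named atomic vectors must become JSON objects to keep their names
  for (s in c("promoterClass", "islandRegime", "probeCategory",
              "normalBeta", "tumourBeta", "plantedChange", "bivalentFlag",
              "tet2Flag", "probeGene"))
    if (!is.null(truth[[s]])) truth[[s]] <- as.list(truth[[s]])
  truth$totalMapped <- lapply(readSets(cohort), totalMapped)
  truth$plantedIslands <- data.frame(
    chrom = as.character(seqnames(truth$plantedIslands)),
    start = start(truth$plantedIslands), end = end(truth$plantedIslands),
    regime = truth$plantedIslands$regime,
    gene_id = truth$plantedIslands$gene_id)
  write_json(truth, file.path(dir, "truth.json"), auto_unbox = FALSE,
             digits = NA, pretty = TRUE)
  writeSimConfig(simConfig(cohort), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort input bundle from disk
#'
#' Reconstructs an \linkS4class{HmcCohort} from the files written by
#' \code{\link{writeCohort}}. A missing file aborts with the input stage
#' named.
#'
#' @param dir directory containing the bundle.
#' @return an \linkS4class{HmcCohort}.
#' @export
readCohort <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p))
      stop("stage 'input': missing required file ", f, call. = FALSE)
    p
  }
  config <- readSimConfig(need("config.yaml"))
  genome <- readDNAStringSet(need("genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  gdf <- read.delim(need("genes.tsv"))
  genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand, gene_id = gdf$gene_id,
                   tss = gdf$tss, tts = gdf$tts)
  seqlens <- setNames(Biostrings::width(genome), names(genome))
  seqlengths(genes) <- seqlens[seqlevels(genes)]
  truth <- read_json(need("truth.json"), simplifyVector = TRUE)
  for (s in c("promoterClass", "islandRegime", "probeCategory",
              "normalBeta", "tumourBeta", "plantedChange", "bivalentFlag",
              "tet2Flag"))
    if (!is.null(truth[[s]])) truth[[s]] <- unlist(truth[[s]])
  pi_ <- truth$plantedIslands
  truth$plantedIslands <- if (length(pi_) && nrow(as.data.frame(pi_)))
    GRanges(pi_$chrom, IRanges(pi_$start, pi_$end), regime = pi_$regime,
            gene_id = pi_$gene_id) else GRanges()
  readSetFiles <- list.files(dir, pattern = "^reads_.*\\.bed$")
  if (!length(readSetFiles))
    stop("stage 'input': missing read BED files", call. = FALSE)
  readSets <- list()
  for (f in readSetFiles) {
    id <- sub("^reads_(.*)\\.bed$", "\\1", f)
    gr <- import(file.path(dir, f), format = "BED")
    mcols(gr) <- NULL
    seqlengths(gr) <- seqlens[seqlevels(gr)]
    tm <- truth$totalMapped[[id]]
    readSets[[id]] <- AlignedReadSet(id, gr,
                                     totalMapped = if (is.null(tm))
                                       length(gr) else unlist(tm))
  }
  mdf <- read.delim(need("manifest.tsv"))
  probes <- GRanges(mdf$chrom, IRanges(mdf$pos_1based, width = 1L),
                    probe_id = mdf$probe_id, design_type = mdf$design_type,
                    cross_reactive = mdf$cross_reactive, snp = mdf$snp,
                    sex_chrom = mdf$sex_chrom, true_gene = mdf$true_gene)
  seqlengths(probes) <- seqlens[seqlevels(probes)]
  intens <- read.delim(need("intensities.tsv"))
  pairing <- read.delim(need("pairing.tsv"))
  peaksPath <- need("peaks.bed")
  peaks <- if (file.size(peaksPath) > 0)
    import(peaksPath, format = "BED") else GRanges()
  if (length(peaks)) mcols(peaks) <- NULL
  biv <- read.delim(need("bivalent.tsv"))
  truth$probeGene <- setNames(probes$true_gene, probes$probe_id)
  new("HmcCohort", genome = genome, genes = genes, probes = probes,
      readSets = readSets, intensities = intens, pairing = pairing,
      peaks = peaks, bivalentGenes = as.character(biv$gene_id),
      truth = truth, config = config)
}
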