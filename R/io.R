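#' @importFrom data.table fread fwrite as.data.table
NULL

#' Read and write pipeline tables
#'
#' All tables are tab-separated with headers. GWAS summary statistics carry
#' (snp_id, a1, a2, z); the LD panel is a plain sample x SNP dosage matrix
#' with a sidecar SNP table (snp_id, chrom, pos, a1, a2, maf); weight models
#' are one per-gene TSV (snp_id, a1, a2, weight, pos) plus a model-index TSV
#' (gene_id, panel, model_type, cv_r2, cv_p, h2, h2_p, chrom, start, end,
#' strand, file).
#'
#' @param x the object to write.
#' @param path,dir file or directory path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeGwasZ <- function(x, path) fwrite(x, path, sep = "\t")

#' @rdname pipeline-io
#' @export
readGwasZ <- function(path) {
  tab <- as.data.frame(fread(path, sep = "\t"))
  need <- c("snp_id", "a1", "a2", "z")
  if (!all(need %in% names(tab)))
    stop("malformed GWAS table ", path, ": expected columns ",
         paste(need, collapse = ", "))
  tab
}

#' @rdname pipeline-io
#' @export
writeLdPanel <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(as.data.table(x$genotypes), file.path(dir, "dosages.tsv"),
         sep = "\t")
  cols <- intersect(c("snp_id", "chrom", "pos", "a1", "a2", "maf", "block"),
                    names(x$snps))
  fwrite(x$snps[, cols], file.path(dir, "snps.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname pipeline-io
#' @export
readLdPanel <- function(dir) {
  G <- as.matrix(fread(file.path(dir, "dosages.tsv"), sep = "\t"))
  snps <- as.data.frame(fread(file.path(dir, "snps.tsv"), sep = "\t",
                              colClasses = list(character = "chrom")))
  if (ncol(G) != nrow(snps))
    stop("dosage columns do not match the SNP table in ", dir)
  colnames(G) <- snps$snp_id
  list(genotypes = G, snps = snps)
}

#' @rdname pipeline-io
#' @export
writeWeightModels <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- do.call(rbind, lapply(seq_along(x), function(i) {
    m <- x[[i]]
    file <- sprintf("weights_%04d_%s.tsv", i, geneId(m))
    fwrite(modelWeights(m), file.path(dir, file), sep = "\t")
    data.frame(gene_id = geneId(m), panel = m@panel,
               model_type = m@modelType, cv_r2 = m@cvR2, cv_p = m@cvP,
               h2 = m@h2, h2_p = m@h2P, chrom = m@chrom,
               start = m@geneStart, end = m@geneEnd, strand = m@strand,
               file = file, stringsAsFactors = FALSE)
  }))
  fwrite(idx, file.path(dir, "model_index.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname pipeline-io
#' @export
readWeightModels <- function(dir) {
  idx <- as.data.frame(fread(file.path(dir, "model_index.tsv"), sep = "\t",
                             colClasses = list(character = "chrom")))
  lapply(seq_len(nrow(idx)), function(i) {
    w <- as.data.frame(fread(file.path(dir, idx$file[i]), sep = "\t"))
    weightModel(geneId = idx$gene_id[i], weights = w, panel = idx$panel[i],
                modelType = idx$model_type[i], cvR2 = idx$cv_r2[i],
                cvP = idx$cv_p[i], h2 = idx$h2[i], h2P = idx$h2_p[i],
                chrom = idx$chrom[i], geneStart = idx$start[i],
                geneEnd = idx$end[i], strand = idx$strand[i])
  })
}

#' @rdname pipeline-io
#' @export
writeTruth <- function(x, path) {
  fwrite(data.frame(
    gene_id = x$causalGenes,
    effect = as.numeric(x$effect[x$causalGenes]),
    enriched = x$causalGenes %in% x$enrichedGeneSet,
    stringsAsFactors = FALSE), path, sep = "\t")
}

#' Write a complete synthetic study to a directory
#'
#' Emits the same formats the pipeline reads: the LD panel, the weight
#' models, the GWAS Z table and the planted truth.
#'
#' @param sim a \linkS4class{TwasSimulation}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLdPanel(list(genotypes = sim@genotypes, snps = sim@snps),
               file.path(dir, "panel"))
  writeWeightModels(sim@models, file.path(dir, "models"))
  writeGwasZ(sim@gwas, file.path(dir, "gwas_z.tsv"))
  writeTruth(sim@truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Write pipeline reports
#'
#' Emits the master results TSV (one row per tested gene with marginal,
#' permutation, joint-conditional and colocalization columns), a per-locus
#' residual TSV (snp_id, z_marginal, z_residual) for locus plots, an
#' enrichment TSV when the enrichment stage ran, and a YAML run manifest
#' (options echo plus stage tallies) sufficient to re-run the analysis.
#'
#' @param results a \linkS4class{TwasResults}.
#' @param outDir output directory (created if needed).
#' @return character vector of written files, invisibly.
#' @export
writeReports <- function(results, outDir) {
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)
  files <- character()
  master <- file.path(outDir, "master_results.tsv")
  fwrite(resultsTable(results), master, sep = "\t", na = "NA")
  files <- c(files, master)
  for (l in lociReports(results)) {
    f <- file.path(outDir, sprintf("locus_%s_residual.tsv", l$locus_id))
    fwrite(l$residual, f, sep = "\t")
    files <- c(files, f)
  }
  enr <- enrichmentTable(results)
  if (!is.null(enr)) {
    f <- file.path(outDir, "enrichment.tsv")
    fwrite(enr, f, sep = "\t")
    files <- c(files, f)
  }
  manifest <- file.path(outDir, "run_manifest.yaml")
  yaml::write_yaml(list(
    options = attr(results, "options"),
    tallies = stageTallies(results),
    proportion_explained = lapply(lociReports(results),
                                  function(l) l$proportion_explained),
    log = as.list(results@log)), manifest)
  files <- c(files, manifest)
  invisible(files)
}

#' @rdname pipeline-io
#' @export
readMasterResults <- function(path) {
  as.data.frame(fread(path, sep = "\t", na.strings = "NA",
                      colClasses = list(character = "chrom")))
}

#' Run the pipeline from a YAML configuration file
#'
#' The configuration lists input paths (\code{gwas_z}, \code{ld_panel},
#' \code{models}, optional \code{known_gwas_loci}) and any
#' \code{\link{pipelineOptions}} overrides under \code{thresholds}, plus a
#' \code{seed}.
#'
#' @param configPath path to the YAML file.
#' @param outDir optional report directory; when given,
#'   \code{\link{writeReports}} is called.
#' @return a \linkS4class{TwasResults}.
#' @export
runPipelineFromConfig <- function(configPath, outDir = NULL) {
  cfg <- yaml::read_yaml(configPath)
  gwas <- readGwasZ(cfg$gwas_z)
  panel <- readLdPanel(cfg$ld_panel)
  models <- readWeightModels(cfg$models)
  known <- NULL
  if (!is.null(cfg$known_gwas_loci)) {
    known <- as.data.frame(fread(cfg$known_gwas_loci, sep = "\t",
                                 colClasses = list(character = "chrom")))
  }
  opts <- do.call(pipelineOptions,
                  c(cfg$thresholds %||% list(),
                    list(seed = as.integer(cfg$seed %||% 1L))))
  res <- runPipeline(gwas = gwas, panel = panel, models = models,
                     knownLoci = known, options = opts)
  if (!is.null(outDir)) writeReports(res, outDir)
  res
}
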