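# Orchestration: per-cell measurement of one multi-channel stack, and the
# two report-bundle entry points (positioning and expression). Configs are
# plain lists or YAML files; every report echoes the configuration and seed
# that produced it, so runs are self-describing and reproducible.

.defaultSegmentation <- list(threshold_method = "otsu", min_voxels = 50L,
                             min_voxels_locus = 10L)

#' Measure one multi-channel nucleus stack
#'
#' Segments the nucleus channel (Otsu by default, holes filled), each
#' territory channel (26-connected components above the voxel floor), and
#' optional locus/lamina channels, then measures percent radial distance,
#' sub-shell, and volume per territory copy, and locus-to-lamina distances
#' per locus spot. One nucleus per stack is assumed (individually cropped
#' nuclei).
#'
#' @param stacks a [StackSet-class].
#' @param roles list mapping channel roles to channel names: `nucleus`
#'   (single name), `territories` (character vector), optional `lamina` and
#'   `loci` (single names).
#' @param segmentation list with `threshold_method` ("otsu" or "fixed"),
#'   `fixed_value` (when fixed), `min_voxels` (territories, default 50),
#'   `min_voxels_locus` (default 10).
#' @param imageId identifier carried into the output tables.
#' @return list with `territories` (data.frame: image id, channel, copy
#'   index, X, Y, rd_percent, shell, volume), `loci` (data.frame or NULL),
#'   `nucleus` (volume and centroid).
#' @export
analyzeCell <- function(stacks, roles, segmentation = list(),
                        imageId = "cell") {
  stopifnot(is(stacks, "StackSet"))
  seg <- utils::modifyList(.defaultSegmentation, segmentation)
  missingCh <- setdiff(unlist(roles), channelNames(stacks))
  if (length(missingCh))
    stop("[", imageId, "] channel(s) not in stack: ",
         paste(missingCh, collapse = ", "))
  vs <- voxelSize(stacks)
  dims <- dim(stacks)
  thr <- function(img) {
    if (seg$threshold_method == "fixed")
      thresholdChannel(img, "fixed", value = seg$fixed_value)
    else thresholdChannel(img, "otsu")
  }

  nucImg <- stacks[[roles$nucleus]]
  nuc <- tryCatch(nucleusObject(thr(nucImg), img = nucImg),
                  error = function(e)
                    stop("[", imageId, "] nucleus segmentation: ",
                         conditionMessage(e)))
  nucMask <- .fillHoles3D(objectMask(nuc, dims))
  A <- centroidUm(nuc)

  terrRows <- NULL
  for (ch in roles$territories) {
    img <- stacks[[ch]]
    objs <- labelObjects(thr(img), img = img, minVoxels = seg$min_voxels)
    for (o in objs) {
      rm <- radialDistance(nucMask, A, centroidUm(o), vs)
      terrRows <- rbind(terrRows, data.frame(
        image_id = imageId, chromosome = ch, copy_index = o@label,
        X_um = rm@X_um, Y_um = rm@Y_um, rd_percent = rm@rdPercent,
        shell = as.character(shellOf(rm@rdPercent)),
        volume_um3 = volumeUm3(o)))
    }
    if (length(objs) == 0L)
      terrRows <- rbind(terrRows, data.frame(
        image_id = imageId, chromosome = ch, copy_index = NA_integer_,
        X_um = NA_real_, Y_um = NA_real_, rd_percent = NA_real_,
        shell = NA_character_, volume_um3 = NA_real_))
  }

  lociRows <- NULL
  if (!is.null(roles$loci)) {
    anchorMask <-
      if (!is.null(roles$lamina)) thr(stacks[[roles$lamina]]) else
        .surfaceMaskFromNucleus(nucMask)
    locImg <- stacks[[roles$loci]]
    spots <- labelObjects(thr(locImg), img = locImg,
                          minVoxels = seg$min_voxels_locus)
    for (s in spots) {
      lm <- laminaDistance(centerOfMassUm(s), anchorMask, vs,
                           anchorChannel = if (!is.null(roles$lamina))
                             roles$lamina else "nucleus_surface")
      lociRows <- rbind(lociRows, data.frame(
        image_id = imageId, spot = s@label,
        cm_z = lm$cm_um[1], cm_y = lm$cm_um[2], cm_x = lm$cm_um[3],
        distance_um = lm$distance_um, anchor = lm$anchor_channel))
    }
  }

  list(territories = terrRows, loci = lociRows,
       nucleus = list(volume_um3 = volumeUm3(nuc), centroid_um = A))
}

# fall-back anchor when no lamina channel: the nucleus boundary itself
.surfaceMaskFromNucleus <- function(nucMask) {
  d <- dim(nucMask)
  surf <- .surfaceVoxels(nucMask)
  m <- array(FALSE, d)
  m[surf] <- TRUE
  m
}

.loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

#' Run the positioning pipeline over a cohort
#'
#' Accepts either a simulation block (`simulate`) or a vector of TIFF paths
#' (`inputs`), measures every cell with [analyzeCell()], and assembles the
#' report bundle: the per-territory measurements table, per-condition shell
#' distribution, median/IQR table, volume table, and the ploidy cohort
#' table. With `output_dir` set, the tables are written as CSV plus a JSON
#' run log (configuration echo, package version, seed).
#'
#' @param config list or YAML path. Fields: `condition` (label), `roles`
#'   (see [analyzeCell()]), `segmentation`, `seed`, and one of `simulate`
#'   (arguments for [simulateCohort()], e.g. `n_cells`, `chromosome`,
#'   `gain_fraction`) or `inputs` (TIFF paths).
#' @return report list with `measurements`, `nuclei`, `shell_distribution`,
#'   `median_iqr`, `volumes`, `ploidy_calls`, `ploidy_summary`, `config`.
#' @export
runPositioning <- function(config) {
  config <- .loadConfig(config)
  if (is.null(config$roles)) stop("config must define channel roles")
  condition <- if (is.null(config$condition)) "condition" else config$condition
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  cells <- list()
  truths <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    acq <- do.call(acquisitionSpec,
                   c(sim$acquisition, list(seed = seed)))
    args <- sim[setdiff(names(sim), c("acquisition"))]
    args$acq <- acq
    names(args)[names(args) == "n_cells"] <- "nCells"
    names(args)[names(args) == "gain_fraction"] <- "gainFraction"
    simOut <- do.call(simulateCohort, args)
    cells <- lapply(simOut, `[[`, "stacks")
    truths <- lapply(simOut, `[[`, "truth")
  } else if (!is.null(config$inputs)) {
    if (length(config$inputs) == 0L) stop("empty input set")
    cells <- lapply(config$inputs, readStack)
  } else stop("config must provide either 'simulate' or 'inputs'")
  if (length(cells) == 0L) stop("empty input set")

  seg <- if (is.null(config$segmentation)) list() else config$segmentation
  terr <- NULL; loci <- NULL; nucRows <- NULL
  for (i in seq_along(cells)) {
    id <- sprintf("%s_cell%03d", condition, i)
    res <- analyzeCell(cells[[i]], config$roles, seg, imageId = id)
    terr <- rbind(terr, res$territories)
    loci <- rbind(loci, res$loci)
    nucRows <- rbind(nucRows, data.frame(
      image_id = id, volume_um3 = res$nucleus$volume_um3))
  }
  measured <- terr[!is.na(terr$rd_percent), , drop = FALSE]

  shellDist <- shellDistribution(measured$rd_percent, condition)
  medIqr <- medianIQRTable(measured$rd_percent,
                           paste(condition, measured$chromosome))
  volTab <- medianIQRTable(measured$volume_um3,
                           paste(condition, measured$chromosome))
  copyCounts <- stats::aggregate(
    copy_index ~ image_id + chromosome, data = terr,
    FUN = function(x) sum(!is.na(x)), na.action = stats::na.pass)
  calls <- callPloidy(copyCounts$copy_index, copyCounts$image_id,
                      copyCounts$chromosome)

  report <- list(measurements = terr, loci = loci, nuclei = nucRows,
                 shell_distribution = shellDist,
                 median_iqr = medIqr, volumes = volTab,
                 ploidy_calls = calls, ploidy_summary = ploidySummary(calls),
                 truths = truths,
                 config = config, seed = seed,
                 version = as.character(utils::packageVersion("ctRadial")))
  if (!is.null(config$output_dir)) .writePositioningBundle(report, config)
  report
}

.writePositioningBundle <- function(report, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) utils::write.csv(
    x, file.path(config$output_dir, f), row.names = FALSE)
  wr(report$measurements, "measurements.csv")
  if (!is.null(report$loci)) wr(report$loci, "loci.csv")
  wr(report$nuclei, "nuclei.csv")
  sd <- report$shell_distribution
  wr(data.frame(condition = sd@condition, shell = names(sd@counts),
                count = sd@counts), "shell_distribution.csv")
  wr(report$median_iqr, "median_iqr.csv")
  wr(report$volumes, "volumes.csv")
  wr(report$ploidy_calls, "ploidy_calls.csv")
  wr(report$ploidy_summary, "ploidy_summary.csv")
  jsonlite::write_json(
    list(version = report$version, seed = report$seed, config = config),
    file.path(config$output_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}

#' Run the expression pipeline
#'
#' Filters each gene table with the standard cutoffs, computes the
#' per-chromosome deregulation profile and its gene-density r^2, and — when
#' two tables are supplied — the overlap of their deregulated sets.
#'
#' @param config list or YAML path. Fields: `gene_tables` (named list of
#'   TSV paths or data.frames), `annotation` (path or data.frame),
#'   `fc_cutoff` (default 2), `p_cutoff` (default 0.05), `dereg_threshold`
#'   (default 0.7), optional `output_dir`.
#' @return report list with per-table `profiles`, `dereg_sets`, `r_squared`,
#'   pairwise `overlap` (when >= 2 tables), and the echoed cutoffs.
#' @export
runExpression <- function(config) {
  config <- .loadConfig(config)
  if (is.null(config$gene_tables) || length(config$gene_tables) == 0L)
    stop("config must provide gene_tables")
  if (is.null(config$annotation)) stop("config must provide an annotation")
  ann <- config$annotation
  if (is.character(ann)) ann <- readAnnotation(ann)
  fcCut <- if (is.null(config$fc_cutoff)) 2.0 else config$fc_cutoff
  pCut <- if (is.null(config$p_cutoff)) 0.05 else config$p_cutoff
  thr <- if (is.null(config$dereg_threshold)) 0.7 else config$dereg_threshold

  tabs <- lapply(config$gene_tables, function(x)
    if (is.character(x)) readGeneTable(x) else x)
  if (is.null(names(tabs)) || any(!nzchar(names(tabs))))
    names(tabs) <- paste0("table", seq_along(tabs))

  profiles <- list(); deregSets <- list(); r2 <- list()
  for (nm in names(tabs)) {
    fl <- filterDeregulated(tabs[[nm]], fcCut, pCut)
    dereg <- rbind(fl$up, fl$down)
    deregSets[[nm]] <- dereg
    profiles[[nm]] <- percentDeregulation(dereg, ann, threshold = thr)
    r2[[nm]] <- tryCatch(densityCorrelation(profiles[[nm]], ann),
                         error = function(e) NULL)
  }
  overlap <- NULL
  if (length(tabs) >= 2L)
    overlap <- overlapGenes(deregSets[[1]]$gene_id, deregSets[[2]]$gene_id)

  report <- list(profiles = profiles, dereg_sets = deregSets,
                 r_squared = r2, overlap = overlap,
                 cutoffs = list(fc_cutoff = fcCut, p_cutoff = pCut,
                                dereg_threshold = thr))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(profiles))
      utils::write.csv(profiles[[nm]],
                       file.path(config$output_dir,
                                 paste0("deregulation_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(overlap = overlap[c("unique_to_a", "unique_to_b", "common",
                               "n_a", "n_b")],
           r_squared = lapply(r2, function(x) x$r_squared),
           cutoffs = report$cutoffs),
      file.path(config$output_dir, "expression_summary.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
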