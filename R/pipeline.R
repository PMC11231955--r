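#' Default pipeline configuration
#'
#' @param out_dir output directory for artifacts.
#' @param stages stages to run, in dependency order; a subset of
#'   `c("phantom", "fc", "lvc", "stats", "eval")`.
#' @param window HU activation window.
#' @param generations GSN walk length.
#' @param phantom a [phantom_spec()] (used by the phantom stage).
#' @param ct_path,seed,lobes_path,vessel_path explicit inputs for the fc
#'   / lvc / stats stages; filled in from the phantom stage when it runs.
#' @param pred_path,gt_path label maps for the eval stage; when omitted
#'   and a phantom was generated, the phantom's own lobe map is evaluated
#'   against itself as a self-consistency check.
#' @param compress write `.nii.gz` instead of `.nii`.
#' @param force overwrite existing artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, stages = c("phantom", "fc", "lvc", "stats",
                                           "eval"),
                       window = c(0, 200), generations = 3L,
                       phantom = phantom_spec(), ct_path = NULL, seed = NULL,
                       lobes_path = NULL, vessel_path = NULL,
                       pred_path = NULL, gt_path = NULL,
                       compress = FALSE, force = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (window[1] >= window[2]) stop("invalid HU window")
  if (generations < 1L) stop("generations must be >= 1")
  structure(
    list(out_dir = out_dir, stages = stages, window = as.numeric(window),
         generations = as.integer(generations), phantom = phantom,
         ct_path = ct_path, seed = seed, lobes_path = lobes_path,
         vessel_path = vessel_path, pred_path = pred_path,
         gt_path = gt_path, compress = compress, force = force),
    class = "run_config")
}

write_provenance <- function(path, stage, inputs, params) {
  side <- paste0(path, ".prov.json")
  obj <- list(artifact = basename(path), stage = stage, inputs = inputs,
              parameters = params,
              software = paste0("lvcmap ",
                                as.character(utils::packageVersion("lvcmap"))))
  jsonlite::write_json(obj, side, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(side)
}

artifact_path <- function(cfg, name) {
  ext <- if (cfg$compress) ".nii.gz" else ".nii"
  file.path(cfg$out_dir, paste0(name, ext))
}

check_overwrite <- function(cfg, paths) {
  existing <- paths[file.exists(paths)]
  if (length(existing) && !cfg$force)
    stop("artifacts already exist (use force = TRUE to overwrite): ",
         paste(basename(existing), collapse = ", "))
}

#' Run the LVC pipeline
#'
#' Chains the requested stages in dependency order: phantom generation,
#' fuzzy-connectedness propagation, LVC vector field, per-lobe
#' orientation statistics, and segmentation evaluation. Every artifact
#' gets a JSON provenance sidecar recording its inputs and parameters,
#' and identical configurations produce byte-identical artifacts.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("cfg must be a run_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  arts <- list()
  bundle <- NULL
  ct <- NULL; seed <- cfg$seed; lobes <- NULL; vessel <- NULL

  if ("phantom" %in% cfg$stages) {
    paths <- c(ct = artifact_path(cfg, "ct"),
               lobes = artifact_path(cfg, "lobes"),
               vessels = artifact_path(cfg, "vessels"),
               seed = file.path(cfg$out_dir, "seed.json"),
               directions = file.path(cfg$out_dir, "directions.json"))
    check_overwrite(cfg, paths)
    bundle <- generate_phantom(cfg$phantom)
    write_volume(bundle$ct, paths["ct"])
    write_label_map(bundle$lobes, paths["lobes"])
    vm <- lobe_label_map(array(as.integer(bundle$vessel_mask),
                               dim = cfg$phantom$dims),
                         cfg$phantom$spacing)
    write_label_map(vm, paths["vessels"])
    jsonlite::write_json(list(seed = bundle$seed), paths["seed"],
                         auto_unbox = FALSE, digits = NA)
    dirs <- as.data.frame(bundle$planted_directions)
    names(dirs) <- c("dx", "dy", "dz")
    dirs$lobe <- rownames(bundle$planted_directions)
    jsonlite::write_json(dirs[, c("lobe", "dx", "dy", "dz")],
                         paths["directions"], auto_unbox = TRUE, digits = NA)
    for (p in paths)
      write_provenance(p, "phantom", inputs = list(),
                       params = list(rng_seed = cfg$phantom$rng_seed,
                                     dims = cfg$phantom$dims))
    ct <- bundle$ct; seed <- bundle$seed; lobes <- bundle$lobes
    vessel <- bundle$vessel_mask
    arts <- c(arts, as.list(paths))
  }

  need_ct <- function() {
    if (is.null(ct)) {
      if (is.null(cfg$ct_path)) stop("fc stage: no CT input configured")
      if (!file.exists(cfg$ct_path))
        stop("fc stage: missing input file ", cfg$ct_path)
      ct <<- read_volume(cfg$ct_path)
    }
  }

  fc <- NULL
  if ("fc" %in% cfg$stages) {
    need_ct()
    if (is.null(seed)) stop("fc stage: no seed configured")
    paths <- c(fc_codes = artifact_path(cfg, "fc_codes"),
               fc_strength = artifact_path(cfg, "fc_strength"))
    check_overwrite(cfg, paths)
    fc <- compute_fc(ct, seed, cfg$window)
    codes_img <- nifti_from_grid(fc$codes, fc$spacing, fc$origin)
    RNifti::writeNifti(codes_img, paths["fc_codes"], datatype = "uint8")
    write_volume(ct_volume(fc$strength, fc$spacing, fc$origin),
                 paths["fc_strength"])
    for (p in paths)
      write_provenance(p, "fc", inputs = list(ct = "ct"),
                       params = list(seed = seed, window = cfg$window))
    arts <- c(arts, as.list(paths))
  }

  lvc <- NULL
  if ("lvc" %in% cfg$stages) {
    if (is.null(fc)) stop("lvc stage requires the fc stage")
    if (is.null(vessel)) {
      if (is.null(cfg$vessel_path)) stop("lvc stage: no vessel mask configured")
      vessel <- read_label_map(cfg$vessel_path)$labels > 0L
    }
    path <- artifact_path(cfg, "lvc")
    check_overwrite(cfg, path)
    lvc <- compute_lvc(fc, vessel, cfg$generations)
    write_vector_field(lvc, path)
    write_provenance(path, "lvc", inputs = list(fc = "fc_codes"),
                     params = list(generations = cfg$generations))
    arts$lvc <- path
  }

  if ("stats" %in% cfg$stages) {
    if (is.null(lvc)) stop("stats stage requires the lvc stage")
    if (is.null(lobes)) {
      if (is.null(cfg$lobes_path)) stop("stats stage: no lobe map configured")
      lobes <- read_label_map(cfg$lobes_path)
    }
    path <- file.path(cfg$out_dir, "orient.csv")
    check_overwrite(cfg, path)
    ori <- lobe_average_orientation(lvc, lobes, vessel)
    utils::write.csv(ori, path, row.names = FALSE)
    write_provenance(path, "stats", inputs = list(lvc = "lvc"),
                     params = list())
    arts$orient <- path
  }

  if ("eval" %in% cfg$stages) {
    pred <- gt <- NULL
    if (!is.null(cfg$pred_path) && !is.null(cfg$gt_path)) {
      for (p in c(cfg$pred_path, cfg$gt_path))
        if (!file.exists(p)) stop("eval stage: missing input file ", p)
      pred <- read_label_map(cfg$pred_path)
      gt <- read_label_map(cfg$gt_path)
    } else if (!is.null(lobes)) {
      pred <- gt <- lobes   # self-consistency check on the phantom
    } else stop("eval stage: no prediction/ground-truth configured")
    path <- file.path(cfg$out_dir, "report.json")
    check_overwrite(cfg, path)
    rep <- per_lobe_report(pred, gt)
    jsonlite::write_json(
      list(per_lobe = rep$per_lobe, global_dice = rep$global_dice,
           global_asd = rep$global_asd),
      path, auto_unbox = TRUE, digits = NA, na = "null")
    write_provenance(path, "eval", inputs = list(), params = list())
    arts$report <- path
  }

  invisible(arts)
}
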