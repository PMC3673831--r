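# End-to-end orchestration: simulate -> quantify -> airways -> fit, with
# structured JSON reports and a run manifest.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "copdct-run",
    write_volumes = FALSE,
    phantom = list(
      spacing = 0.3,
      lung_hu_insp = -875, lung_hu_exp = -700,
      emphysema_fraction = 0.05, noise_sd = 0
    ),
    densitometry = list(threshold_hu = -950, denoise_sd_mm = 0),
    airway = list(section_spacing_mm = 1.0, n_rays = 72,
                  bifurcation_margin_mm = 2.0),
    cohort = list(n = 1140L),
    fit = list(B = 500L, stratify = TRUE)
  )
}

# Shallow-merge user config over defaults (one level of nesting).
merge_config <- function(user, defaults = default_run_config()) {
  out <- defaults
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(out[[nm]])) {
      out[[nm]] <- utils::modifyList(out[[nm]], user[[nm]])
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

#' Read a run configuration from YAML
#'
#' Unspecified fields fall back to the package defaults (threshold
#' -950 HU, 1-mm section spacing, 72 rays, 500 bootstrap iterations).
#'
#' @param path YAML file path.
#' @return config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_copdct(paste("config file not found:", path), "copdct_missing_input")
  merge_config(yaml::read_yaml(path))
}

#' Run the full pipeline end to end
#'
#' Executes simulate-phantom -> quantify -> airways and simulate-cohort ->
#' fit, writing `metrics.json`, `airway.json`, `ladder.json`, `cohort.csv`
#' and a run manifest (seed, config, package version) into
#' `config$out_dir`. All stages are seeded from `config$seed`.
#'
#' @param config a config list (see [read_run_config()]); missing entries
#'   take package defaults.
#' @return (invisibly) list with the three report objects and the paths
#'   written.
#' @export
run_end_to_end <- function(config = list()) {
  cfg <- merge_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # --- simulate phantom + densitometry -------------------------------
  spec <- standard_wall_phantom(
    spacing = cfg$phantom$spacing,
    lung_hu_insp = cfg$phantom$lung_hu_insp,
    lung_hu_exp = cfg$phantom$lung_hu_exp,
    emphysema_fraction = cfg$phantom$emphysema_fraction,
    noise_sd = cfg$phantom$noise_sd
  )
  ph <- generate_phantom(spec, seed = cfg$seed)

  insp <- ph$insp; expv <- ph$exp
  if (cfg$densitometry$denoise_sd_mm > 0) {
    insp <- denoise_volume(insp, cfg$densitometry$denoise_sd_mm, mask = ph$mask)
    expv <- denoise_volume(expv, cfg$densitometry$denoise_sd_mm, mask = ph$mask)
  }
  metrics <- compute_density_metrics(insp, expv, ph$mask, ph$mask,
                                     threshold_hu = cfg$densitometry$threshold_hu)
  paths$metrics <- file.path(cfg$out_dir, "metrics.json")
  jsonlite::write_json(c(list(schema_version = 1L, seed = cfg$seed),
                         unclass(metrics)),
                       paths$metrics, auto_unbox = TRUE, digits = NA)
  if (isTRUE(cfg$write_volumes)) {
    paths$insp <- write_volume(ph$insp, file.path(cfg$out_dir, "insp.nii.gz"))
    paths$exp <- write_volume(ph$exp, file.path(cfg$out_dir, "exp.nii.gz"))
    paths$mask <- write_volume(ph$mask + 0L, file.path(cfg$out_dir, "mask.nii.gz"),
                               spacing = ph$insp$spacing)
  }

  # --- airway quantification -----------------------------------------
  # segment and trace each tube from a seed just inside its lumen; the
  # phantom tubes stand in for measurable bronchi (generation 2)
  sections <- list()
  for (ti in seq_along(spec$tubes)) {
    tb <- spec$tubes[[ti]]
    u <- (tb$end - tb$start) / sqrt(sum((tb$end - tb$start)^2))
    seed_pt <- tb$start + u  # 1 mm inside
    lumen <- segment_lumen(ph$insp, seed_pt)
    tree <- extract_centerline(lumen, ph$insp$spacing, seed_point = seed_pt)
    tree$branches$generation_label[] <- tb$generation_label
    tree$nodes$generation_label[] <- tb$generation_label
    sections[[ti]] <- sample_cross_sections(tree, cfg$airway$section_spacing_mm)
    sections[[ti]]$branch_id <- ti
  }
  sections <- do.call(rbind, sections)
  sections <- measure_sections(ph$insp, sections, n_rays = cfg$airway$n_rays)
  filt <- filter_cross_sections(sections, cfg$airway$bifurcation_margin_mm)
  pi10 <- compute_pi10(filt$valid, exclusion_tally = filt$tally)
  paths$airway <- file.path(cfg$out_dir, "airway.json")
  jsonlite::write_json(list(
    schema_version = 1L, seed = cfg$seed,
    n_sections = nrow(sections),
    exclusion_tally = as.list(filt$tally),
    pi10 = list(slope = pi10$slope, intercept = pi10$intercept,
                pi10_mm = pi10$pi10_mm,
                n_sections_used = pi10$n_sections_used),
    truth = lapply(ph$truth$tubes, function(t)
      list(pi_mm = t$lumen_perimeter_mm, sqrt_wa_mm = t$sqrt_wa_mm))
  ), paths$airway, auto_unbox = TRUE, digits = NA)

  # --- cohort + diagnostic ladder ------------------------------------
  cohort <- generate_cohort(cohort_config(n = cfg$cohort$n,
                                          seed = cfg$seed + 1000L))
  paths$cohort <- file.path(cfg$out_dir, "cohort.csv")
  write_cohort(cohort, paths$cohort)
  ladder <- run_model_ladder(cohort, B = cfg$fit$B, seed = cfg$seed,
                             stratify = isTRUE(cfg$fit$stratify))
  paths$ladder <- file.path(cfg$out_dir, "ladder.json")
  jsonlite::write_json(ladder_report_to_list(ladder), paths$ladder,
                       auto_unbox = TRUE, digits = NA)

  # --- manifest ------------------------------------------------------
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    schema_version = 1L,
    package = "copdct",
    version = as.character(utils::packageVersion("copdct")),
    seed = cfg$seed,
    config = cfg,
    config_hash = config_hash(cfg_json)
  ), paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(metrics = metrics, pi10 = pi10, ladder = ladder,
                 paths = paths))
}

# Content hash of the serialized config (FNV-1a over the JSON bytes; no
# cryptographic requirement, just provenance fingerprinting).
config_hash <- function(json) {
  bytes <- as.integer(charToRaw(as.character(json)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
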