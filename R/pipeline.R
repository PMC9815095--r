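# Pipeline stages behind the command-line interface, a shared run
# configuration, and the packaged planted-shift recovery experiment.

#' Pipeline run configuration
#'
#' Protocol constants with their published defaults: 19-residue smoothing
#' window, -0.5 attention threshold on the windowed score, trim rule
#' removing non-positive scores, GDT-HA thresholds 0.5/1/2/4 A, and the
#' misalignment rule (>2 A, runs of >= 4).
#'
#' @param window smoothing window (odd).
#' @param flag_threshold windowed-score threshold for low confidence.
#' @param trim_rule `"le0"` or `"lt0"`.
#' @param misalign_dist displacement threshold in Angstrom.
#' @param misalign_min_run minimum inconsistent run length.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param seed RNG seed echoed into manifests.
#' @return a `run_config` list.
#' @export
run_config <- function(window = 19, flag_threshold = -0.5,
                       trim_rule = c("le0", "lt0"), misalign_dist = 2.0,
                       misalign_min_run = 4,
                       interpolation = c("trilinear", "nearest"), seed = 1) {
  structure(list(window = as.integer(window),
                 flag_threshold = flag_threshold,
                 trim_rule = match.arg(trim_rule),
                 gdt_thresholds = c(0.5, 1, 2, 4),
                 misalign_dist = misalign_dist,
                 misalign_min_run = as.integer(misalign_min_run),
                 interpolation = match.arg(interpolation),
                 seed = as.integer(seed)),
            class = "run_config")
}

write_manifest <- function(path, stage, config, inputs, outputs) {
  jsonlite::write_json(list(stage = stage, config = unclass(config),
                            inputs = inputs, outputs = outputs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score a model and write the track
#'
#' @param model_path PDB/mmCIF file.
#' @param chain chain id.
#' @param prob_path probability-volume manifest (`.json`) or table (`.tsv`).
#' @param out output TSV path.
#' @param config a `run_config`.
#' @return the smoothed `score_track`, invisibly.
#' @export
run_score <- function(model_path, chain, prob_path, out,
                      config = run_config()) {
  model <- load_model(model_path, chain)
  vol <- load_probability_volume(prob_path)
  track <- daq_score(model, vol, window = config$window,
                     interpolation = config$interpolation)
  write_track(track, out, threshold = config$flag_threshold)
  write_manifest(paste0(out, ".manifest.json"), "score", config,
                 list(model = model_path, chain = chain, prob = prob_path),
                 list(track = out))
  invisible(track)
}

#' Prepare refinement inputs (trimmed template + masked MSA)
#'
#' @param model_path PDB/mmCIF file.
#' @param chain chain id.
#' @param track_path score-track TSV from [run_score()].
#' @param msa_path full A3M/FASTA alignment.
#' @param out_template output PDB for the trimmed template.
#' @param out_msa output A3M for the masked alignment.
#' @param config a `run_config`.
#' @return list with the `trimmed_template` and `masked_msa`, invisibly.
#' @export
run_prep <- function(model_path, chain, track_path, msa_path, out_template,
                     out_msa, config = run_config()) {
  model <- load_model(model_path, chain)
  track <- read_track(track_path)
  tmpl <- trim_template(model, track, rule = config$trim_rule)
  write_model(tmpl$model, out_template)
  msa <- mask_msa(load_msa(msa_path), track)
  write_msa(msa, out_msa)
  write_manifest(paste0(out_template, ".manifest.json"), "prep", config,
                 list(model = model_path, chain = chain, track = track_path,
                      msa = msa_path),
                 list(template = out_template, msa = out_msa,
                      template_status = tmpl$status))
  invisible(list(template = tmpl, msa = msa))
}

#' Evaluate a model against a reference and write the report
#'
#' @param model_path,reference_path PDB/mmCIF files.
#' @param chain,ref_chain chain ids.
#' @param out output JSON path.
#' @param map_path optional TSV of explicit residue correspondences
#'   (model_key, ref_key).
#' @param config a `run_config`.
#' @return the `quality_report`, invisibly.
#' @export
run_evaluate <- function(model_path, chain, reference_path, ref_chain, out,
                         map_path = NULL, config = run_config()) {
  model <- load_model(model_path, chain)
  ref <- load_model(reference_path, ref_chain)
  map <- NULL
  if (!is.null(map_path)) {
    map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                             colClasses = "character")
  }
  rep <- evaluate_model(model, ref, map = map, dist = config$misalign_dist,
                        min_run = config$misalign_min_run)
  write_report(rep, out)
  write_manifest(paste0(out, ".manifest.json"), "evaluate", config,
                 list(model = model_path, reference = reference_path),
                 list(report = out))
  invisible(rep)
}

#' Rank candidate models and emit the final model
#'
#' @param model_paths PDB files of the candidates.
#' @param chain chain id shared by the candidates.
#' @param prob_path probability-volume manifest or table.
#' @param out_ranking output TSV of the ranking.
#' @param out_final output PDB of the selected model.
#' @param config a `run_config`.
#' @return the `candidate_set`, invisibly.
#' @export
run_select <- function(model_paths, chain, prob_path, out_ranking,
                       out_final, config = run_config()) {
  models <- lapply(model_paths, load_model, chain = chain)
  names(models) <- basename(model_paths)
  vol <- load_probability_volume(prob_path)
  set <- rank_candidates(models, vol, window = config$window)
  utils::write.table(set$ranking, out_ranking, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_model(final_model(set), out_final)
  write_manifest(paste0(out_ranking, ".manifest.json"), "select", config,
                 list(models = model_paths, prob = prob_path),
                 list(ranking = out_ranking, final = out_final))
  invisible(set)
}

#' Generate a synthetic fixture set on disk
#'
#' Emits the ground-truth model, a register-shifted and a displaced copy,
#' the oracle probability volume (20 MRC channels + manifest) and a truth
#' JSON recording the planted errors and seed.
#'
#' @param spec a `synthetic_spec` (or path to a JSON file of its fields).
#' @param out_dir output directory.
#' @param shift_region,shift register-shift plant (defaults: 10 residues
#'   in the chain middle, +3).
#' @param displace_region,displacement conformational plant.
#' @return list of generated objects, invisibly.
#' @export
run_simulate <- function(spec, out_dir, shift_region = NULL, shift = 3,
                         displace_region = NULL, displacement = 8) {
  if (is.character(spec)) {
    spec <- do.call(synthetic_spec, jsonlite::read_json(spec,
                                                        simplifyVector = TRUE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- make_backbone(spec)
  n <- spec$n_residues
  if (is.null(shift_region)) {
    mid <- floor(n / 2)
    shift_region <- c(mid - 4, mid + 5)
  }
  if (is.null(displace_region)) displace_region <- c(5, 10)
  vol <- make_probability_volume(model, spec)
  shifted <- inject_register_shift(model, shift_region, shift)
  displaced <- inject_conformational_error(model, displace_region,
                                           displacement, seed = spec$seed)
  write_model(model, file.path(out_dir, "model.pdb"))
  write_model(shifted, file.path(out_dir, "model_register_shift.pdb"))
  write_model(displaced, file.path(out_dir, "model_displaced.pdb"))
  man <- write_probability_volume(vol, file.path(out_dir, "volume"))
  jsonlite::write_json(list(seed = spec$seed, geometry = spec$geometry,
                            n_residues = n,
                            register_shift = list(region = shift_region,
                                                  shift = shift),
                            conformational = list(region = displace_region,
                                                  displacement = displacement)),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, shifted = shifted, displaced = displaced,
                 volume = vol, manifest = man))
}

#' Planted-register-shift recovery experiment
#'
#' The package's core closed-loop check: generate a 100-residue helix and
#' its oracle volume, plant a 10-residue register shift of +3, score the
#' shifted model, and measure how well the windowed DAQ(AA) separates the
#' planted error, how much of it the trimmed template excludes, and whether
#' DAQ-based ranking prefers the clean model.
#'
#' @param seed RNG seed for the fixture.
#' @param n chain length.
#' @param region planted region (residue numbers `c(from, to)`).
#' @param shift register offset.
#' @param window smoothing window.
#' @return list of measured quantities: `frac_shifted_negative`,
#'   `frac_unshifted_positive`, `template_excluded_frac`,
#'   `clean_ranked_first` (0/1), `total_clean`, `total_shifted`, plus the
#'   underlying objects (`model`, `shifted`, `volume`, `track_clean`,
#'   `track_shifted`).
#' @export
planted_shift_experiment <- function(seed = 1, n = 100, region = c(41, 50),
                                     shift = 3, window = 19) {
  spec <- synthetic_spec(n_residues = n, geometry = "helix", seed = seed)
  model <- make_backbone(spec)
  vol <- make_probability_volume(model, spec)
  shifted <- inject_register_shift(model, region, shift)
  track_s <- daq_score(shifted, vol, window = window)
  track_c <- daq_score(model, vol, window = window)

  reg <- region[1]:region[2]
  # residues whose assigned type actually changed (the shift can map a type
  # onto itself, which is not an error)
  changed <- reg[shifted$residues$aa[match(reg, shifted$residues$number)] !=
                   model$residues$aa[match(reg, model$residues$number)]]
  e <- track_s$entries
  w <- e$windowed
  frac_neg <- mean(w[e$number %in% changed] < 0)
  frac_pos <- mean(w[!e$number %in% reg] > 0)

  tmpl <- trim_template(shifted, track_s)
  removed_num <- track_s$entries$number[track_s$entries$key %in% tmpl$removed]
  excl <- mean(reg %in% removed_num)

  set <- rank_candidates(list(clean = model, shifted = shifted), vol,
                         window = window)
  list(frac_shifted_negative = frac_neg,
       frac_unshifted_positive = frac_pos,
       template_excluded_frac = excl,
       clean_ranked_first = as.integer(set$ranking$label[1] == "clean"),
       total_clean = set$ranking$total[set$ranking$label == "clean"],
       total_shifted = set$ranking$total[set$ranking$label == "shifted"],
       model = model, shifted = shifted, volume = vol,
       track_clean = track_c, track_shifted = track_s)
}
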