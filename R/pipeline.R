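#' Pipeline run configuration
#'
#' Orchestrates the two-row workflow: model personalization (signal
#' processing, muscle-tendon calibration, contact calibration, activation
#' estimation) followed by treatment optimization (verification, virtual
#' surgery sweep) on a synthetic or user-supplied gait cycle.
#'
#' @param model Fixture name (`"planar9"`, `"frontal3d"`) or a
#'   [walker_model()].
#' @param stages Character vector, a prefix-closed subset of
#'   `c("signals", "calibrate_muscles", "calibrate_contact",
#'   "estimate_activations", "verify", "treat")` in dependency order.
#' @param out_dir Output directory for artifacts and the manifest.
#' @param seed Master seed; per-stage seeds derive from it as
#'   `seed * 100 + stage index`.
#' @param scenarios List of [surgical_scenario()]s for the `treat` stage.
#' @param synth Parameters passed to [generate_gait()].
#' @param budget Named list of solver budgets (`N`, `max_iter`,
#'   `calib_iter`) controlling problem sizes.
#' @return Object of class `run_config`.
#' @export
run_config <- function(model = "planar9",
                       stages = c("signals", "calibrate_muscles",
                                  "calibrate_contact",
                                  "estimate_activations", "verify", "treat"),
                       out_dir = tempfile("hemigait_run_"),
                       seed = 1,
                       scenarios = list(surgical_scenario(psoas_factor = 1)),
                       synth = list(), budget = list()) {
  order_all <- c("signals", "calibrate_muscles", "calibrate_contact",
                 "estimate_activations", "verify", "treat")
  stages <- match.arg(stages, order_all, several.ok = TRUE)
  pos <- match(stages, order_all)
  if (any(diff(sort(pos)) > 1) || sort(pos)[1] != 1)
    stop("stages must form a valid prefix of the dependency chain: ",
         paste(order_all, collapse = " -> "))
  budget <- modifyList(list(N = 14, max_iter = 8, n_outer = 1,
                            calib_iter = 4, calib_muscles = 2), budget)
  structure(list(model = model, stages = stages[order(pos)],
                 out_dir = out_dir, seed = seed, scenarios = scenarios,
                 synth = synth, budget = budget),
            class = "run_config")
}

#' @noRd
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end workflow
#'
#' Executes the configured stages in order; each stage reads only
#' prior-stage artifacts, writes its outputs under the run directory, and
#' records key metrics in the manifest (per-DOF moment RMS, synergy VAF,
#' solver status, gait-measure rows). A stage failure halts downstream
#' stages and the manifest records the partial completion.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), invisibly written as
#'   `manifest.json` in the run directory.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- if (is.character(config$model)) make_fixture(config$model)
  else config$model
  bg <- config$budget
  manifest <- list(config_hash = config_hash(config),
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("hemigait")),
                   stages = list())
  say <- function(...) if (!quiet) message(...)
  art <- new.env()

  # the synthetic data underlying the run (stage 0, always present)
  say("generating synthetic gait")
  art$bundle <- do.call(generate_gait,
                        c(list(model = model, seed = config$seed * 100),
                          config$synth))
  art$observed <- degrade_to_observed(art$bundle)

  run_stage <- function(name, fn) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    say("stage: ", name)
    res <- tryCatch(fn(), error = function(e)
      list(status = "error", message = conditionMessage(e)))
    manifest$stages[[name]] <<- res
    if (identical(res$status, "error"))
      stop("stage '", name, "' failed: ", res$message, call. = FALSE)
    invisible(res)
  }

  halted <- tryCatch({
    run_stage("signals", function() {
      b <- art$bundle
      tt <- timetable(b$time,
                      as.data.frame(t(b$q)),
                      units = rep("rad", nrow(b$q)))
      write_mot(tt, file.path(config$out_dir, "kinematics.mot"))
      grf_tt <- timetable(b$time, list(
        fy_operated = b$grf$operated$force[2, ],
        fy_non_operated = b$grf$non_operated$force[2, ]),
        units = c("N", "N"))
      write_gait_csv(grf_tt, file.path(config$out_dir, "grf.csv"))
      hs <- detect_heel_strikes(b$time, b$grf$operated$force[2, ])
      list(status = "success", n_heel_strikes = length(hs))
    })

    run_stage("calibrate_muscles", function() {
      b <- art$bundle
      obs <- art$observed$observed
      idx <- match(art$observed$manifest$observed_channels,
                   names(model$muscles))
      idx <- idx[seq_len(min(bg$calib_muscles, length(idx)))]
      trial <- list(q = b$q, qd = b$qd, moments = b$tau,
                    emg = b$emg[idx, , drop = FALSE],
                    dt = b$time[2] - b$time[1])
      fit <- calibrate_emg_driven(model, list(trial), muscle_idx = idx,
                                  free = c("emg_scale", "emg_delay"),
                                  max_iter = bg$calib_iter)
      art$calibrated <- fit
      list(status = "success",
           moment_rms = mean(unlist(fit$rms_per_dof)))
    })

    run_stage("calibrate_contact", function() {
      cc <- calibrate_contact(model, art$bundle, N = bg$N,
                              guess_scales = c(1, 1, 1),
                              max_iter = bg$max_iter,
                              n_outer = bg$n_outer)
      art$contact <- cc
      list(status = "success", scales = as.numeric(cc$scales),
           solver_status = cc$solution$status)
    })

    run_stage("estimate_activations", function() {
      b <- art$bundle
      obs_idx <- match(art$observed$manifest$observed_channels,
                       names(model$muscles))
      mir <- mirror_activations(b$activations[obs_idx, , drop = FALSE])
      syn <- extract_synergies(b$activations[obs_idx, , drop = FALSE], 6,
                               seed = config$seed * 100 + 4, restarts = 4)
      art$synergies <- syn
      list(status = "success", vaf = syn$vaf,
           mirror_clamp = mir$clamp_fraction)
    })

    run_stage("verify", function() {
      b <- art$bundle
      spec <- ocp_spec("verification_track", N = bg$N)
      prob <- transcribe(spec, model, b)
      track <- solve_ocp(prob, max_iter = bg$max_iter,
                         n_outer = bg$n_outer)
      spec2 <- ocp_spec("verification_predict", N = bg$N, speed = b$speed)
      prob2 <- transcribe(spec2, model, b)
      track$T_cycle <- track$T
      pred <- solve_ocp(prob2, guess = ocp_initial_guess(prob2, from = track),
                        max_iter = bg$max_iter, n_outer = bg$n_outer)
      art$track <- track; art$predict <- pred
      list(status = "success",
           track_status = track$status, predict_status = pred$status,
           T_track = track$T, T_predict = pred$T,
           objective = pred$objective)
    })

    run_stage("treat", function() {
      if (is.null(art$predict))
        stop("treat requires the verify stage artifacts")
      sw <- run_treatment_sweep(model, art$bundle, art$predict,
                                config$scenarios, seeds = config$seed,
                                N = bg$N, max_iter = bg$max_iter,
                                n_outer = bg$n_outer)
      utils::write.csv(sw$comparison,
                       file.path(config$out_dir, "comparison.csv"),
                       row.names = FALSE)
      if (!is.null(sw$rms_angles))
        utils::write.csv(sw$rms_angles,
                         file.path(config$out_dir, "rms_angles.csv"),
                         row.names = FALSE)
      art$sweep <- sw
      list(status = "success",
           statuses = vapply(sw$results, `[[`, "", "status"),
           comparison = sw$comparison)
    })
    FALSE
  }, error = function(e) {
    manifest$halted <<- conditionMessage(e)
    TRUE
  })

  manifest$completed <- names(manifest$stages)
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "artifacts")],
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$artifacts <- as.list(art)
  invisible(manifest)
}
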