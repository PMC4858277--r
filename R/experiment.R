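#' Run a named experimental condition end to end
#'
#' Executes `n_runs` independent runs of the condition (seeds
#' `base_seed + 0 .. n_runs - 1`), including hare-only pre-evolution when
#' the condition's initialisation calls for it, and optionally writes all
#' artefacts to a directory: one per-generation record CSV and one
#' final-population genome CSV per run, a condition summary CSV, and a
#' machine-readable manifest (condition, profile, seeds, package
#' version) from which the whole experiment can be reproduced.
#'
#' @param condition Condition name (see [condition_preset()]) or a full
#'   [staghunt_config()].
#' @param n_runs Number of independent runs.
#' @param base_seed First master seed.
#' @param profile `"paper"` (published scale) or `"desk"` (miniature, see
#'   [desk_profile()]).
#' @param out_dir Output directory (created); `NULL` to skip writing.
#' @param progress See [evolve()].
#' @return A list of class `experiment_result`: `runs` (list of
#'   `stag_run`), `summary` (a [last_generation_summary()]), and
#'   `manifest`.
#' @export
run_experiment <- function(condition, n_runs = 30, base_seed = 0,
                           profile = c("paper", "desk"), out_dir = NULL,
                           progress = 0) {
  profile <- match.arg(profile)
  if (inherits(condition, "staghunt_config")) {
    cfg0 <- condition
    condition <- cfg0$condition
    preset <- condition_preset(condition)
  } else {
    preset <- condition_preset(condition)
    cfg0 <- condition_config(condition, profile)
  }
  seeds <- base_seed + seq_len(n_runs) - 1
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- cfg0
    cfg$evo$seed <- as.integer(seeds[i])
    runs[[i]] <- if (preset$model == "gt") {
      gt_evolve(cfg, seed = seeds[i],
                init = if (preset$init == "all-hare") "all-hare" else "random")
    } else {
      init_pop <- if (preset$init == "pre-evolved-hare") {
        pre_evolve_hare_only(cfg, seed = seeds[i] + 10^6, progress = progress)
      } else {
        NULL
      }
      evolve(cfg, seed = seeds[i], initial_population = init_pop,
             progress = progress)
    }
  }
  summary <- last_generation_summary(runs, condition)
  manifest <- list(condition = condition,
                   profile = profile,
                   n_runs = n_runs,
                   base_seed = base_seed,
                   seeds = seeds,
                   package_version = as.character(utils::packageVersion("staghunt")),
                   config = yaml::yaml.load(serialize_config(cfg0)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir,
                                   call. = FALSE)
    for (i in seq_len(n_runs)) {
      write_run_record(runs[[i]],
                       file.path(out_dir, sprintf("run-%03d.csv", i)))
      if (runs[[i]]$model == "robotic") {
        write_genomes(runs[[i]],
                      file.path(out_dir, sprintf("genomes-%03d.csv", i)))
      }
    }
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(runs = runs, summary = summary, manifest = manifest),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result condition=", x$manifest$condition,
      " runs=", x$manifest$n_runs, ">\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write / read a per-generation run record as CSV
#'
#' @param run A `stag_run`.
#' @param path Output file.
#' @export
write_run_record <- function(run, path) {
  utils::write.csv(tidy(run), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_record
#' @return `read_run_record()`: the per-generation tibble.
#' @export
read_run_record <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write the final population's genomes as CSV
#'
#' One genome per row; the header records the architecture and weight
#' bound so a snapshot can be decoded and replayed without the original
#' configuration object.
#'
#' @param run A `stag_run` from [evolve()].
#' @param path Output file.
#' @export
write_genomes <- function(run, path) {
  arch <- run$config$controller
  genomes <- do.call(rbind, run$population$genomes)
  colnames(genomes) <- paste0("g", seq_len(ncol(genomes)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# architecture %d-%d-%d w_max %g",
                     arch$n_inputs, arch$n_hidden, arch$n_outputs,
                     arch$w_max), con)
  utils::write.csv(as.data.frame(genomes), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genomes
#' @return `read_genomes()`: a list of genome vectors, with the
#'   architecture string as attribute `"architecture"`.
#' @export
read_genomes <- function(path) {
  header <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#")
  genomes <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, ]))
  attr(genomes, "architecture") <- sub("^# ", "", header)
  genomes
}

#' Write hunt events as JSON-lines
#'
#' One capture event per line: time step, prey kind, cooperative flag,
#' participating hunters and per-hunter reward.
#'
#' @param events An events tibble from [run_episode()].
#' @param path Output file.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  dplyr::bind_rows(lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
}

#' Write hunter trajectories as CSV
#'
#' @param trajectories Trajectory tibble from
#'   `run_episode(..., record_trajectories = TRUE)` (columns step, hunter,
#'   x, y, heading).
#' @param path Output file.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Replay one episode from a genome snapshot
#'
#' Re-simulates a single episode between two genomes of a saved
#' population with trajectory recording on, for behavioural inspection
#' (e.g. the mutual-circling statistic of evolved cooperators).
#'
#' @param genomes A list of genome vectors (see [read_genomes()]) or a
#'   `stag_run`.
#' @param config A [staghunt_config()].
#' @param pair Indices of the two genomes to pair.
#' @param seed Episode seed.
#' @return An `episode_result` with trajectories.
#' @export
replay_episode <- function(genomes, config = staghunt_config(),
                           pair = c(1, 2), seed = 0) {
  if (inherits(genomes, "stag_run")) {
    config <- genomes$config
    genomes <- genomes$population$genomes
  }
  run_episode(genomes[[pair[1]]], genomes[[pair[2]]], config,
              rng = make_rng(seed, "replay"), record_trajectories = TRUE)
}
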