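# Cohort assembly: subjects -> (optionally) raw EMG + force data -> the wide
# cohort table every downstream analysis consumes.

#' Default stimulation grid for simulated sessions
#'
#' A straight 30 mm gyrus-sulcus border at the configured grid origin,
#' turned into the standard 5 x 7 grid. Simulated cohorts use one common
#' grid in MNI-like coordinates; per-subject anatomical variation is carried
#' by the subject's hotspot position instead.
#'
#' @param config a [generator_config()].
#' @return a [build_grid()] result.
#' @export
default_grid <- function(config = generator_config()) {
  o <- config$grid_origin
  curve <- sulcus_curve(cbind(seq(o[1], o[1] + 30, by = 5), o[2], o[3]))
  build_grid(curve)
}

# nearest grid line for a continuous y coordinate
line_from_y <- function(y, config) {
  k <- 1 + round((y - config$grid_origin[2]) / 5)
  pmin(pmax(k, 1), 5)
}

#' Simulate a full cohort
#'
#' Generates `n_subjects` subjects and assembles the wide cohort table. Two
#' fidelity levels are available per data stream:
#'
#' * `emg_level = FALSE` (record level): hotspot coordinates, lines,
#'   amplitudes and latencies are the subjects' generating values.
#' * `emg_level = TRUE`: per-subject EMG sessions are simulated
#'   ([simulate_emg_session()]) and pushed through the full extraction chain
#'   ([analyze_emg_session()]); the table carries the *extracted* hotspot
#'   quantities, measurement error included.
#' * `force_level = FALSE`: the CV columns are the subjects' target CVs;
#'   with `TRUE` force traces are simulated and re-analysed with
#'   [analyze_force_trace()].
#'
#' Subjects lacking quantitative MRI (`n_r1_missing`, drawn at random on a
#' dedicated substream) have `NA` in all R1 columns. The hotspot group
#' (caudal: lines 1-2, rostral: lines 3-5) is taken from the FDI hotspot
#' line. Identical seeds give bit-identical cohorts.
#'
#' @param config a [generator_config()].
#' @param emg_level,force_level simulate raw data and extract, or copy the
#'   generating values (defaults `FALSE`).
#' @param muscles muscles to include, subset of `c("FDI", "ADM")`.
#' @param keep_raw keep raw sessions/traces in the returned object (memory!).
#' @param seed master seed (default `config$seed`).
#' @return an object of class `knob_cohort`: list with `table` (data frame,
#'   one row per subject), `config`, `grid`, `subjects`, and `raw` (list
#'   with `emg` and `force` when `keep_raw = TRUE`).
#' @examples
#' coh <- simulate_cohort(generator_config(n_subjects = 6, n_r1_missing = 0))
#' nrow(coh$table)
#' @export
simulate_cohort <- function(config, emg_level = FALSE, force_level = FALSE,
                            muscles = c("FDI", "ADM"), keep_raw = FALSE,
                            seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  muscles <- match.arg(muscles, several.ok = TRUE)
  n <- config$n_subjects
  grid <- default_grid(config)

  subjects <- lapply(seq_len(n), function(i)
    simulate_subject(config, i, seed = substream_seed(seed, "subject", i)))

  set.seed(substream_seed(seed, "r1missing"))
  r1_na <- if (config$n_r1_missing > 0) sample(n, config$n_r1_missing)
           else integer(0)

  raw <- list(emg = vector("list", n), force = vector("list", n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    row <- list(subject = i, latent_myelin = s$latent_myelin,
                r1_caudal = s$roi_r1_caudal, r1_rostral = s$roi_r1_rostral,
                thickness_caudal = s$thickness_caudal,
                thickness_rostral = s$thickness_rostral,
                curvature_caudal = s$curvature_caudal,
                curvature_rostral = s$curvature_rostral,
                bold_caudal = s$bold_caudal, bold_rostral = s$bold_rostral,
                bold_index = s$bold_index, bold_little = s$bold_little,
                rmt = s$rmt_true)

    if (emg_level) {
      ses <- simulate_emg_session(s, grid, config, muscles = muscles,
                                  seed = substream_seed(seed, "emg", i))
      for (m in muscles) {
        ana <- analyze_emg_session(ses[[m]], grid)
        pre <- tolower(m)
        row[[paste0(pre, "_hotspot_x")]] <- unname(ana$hotspot$position["x"])
        row[[paste0(pre, "_hotspot_y")]] <- ana$hotspot$y_coordinate
        row[[paste0(pre, "_hotspot_line")]] <- ana$hotspot$line_index
        row[[paste0(pre, "_hotspot_amp")]] <- ana$hotspot$mean_amplitude
        row[[paste0(pre, "_latency")]] <- ana$hotspot$shortest_latency
      }
      if (keep_raw) raw$emg[[i]] <- ses
    } else {
      if ("FDI" %in% muscles) {
        row$fdi_hotspot_x <- s$true_hotspot_x
        row$fdi_hotspot_y <- s$true_hotspot_y
        row$fdi_hotspot_line <- line_from_y(s$true_hotspot_y, config)
        row$fdi_hotspot_amp <- s$amp_fdi
        row$fdi_latency <- s$true_latency
      }
      if ("ADM" %in% muscles) {
        row$adm_hotspot_x <- s$adm_hotspot_x
        row$adm_hotspot_y <- s$adm_hotspot_y
        row$adm_hotspot_line <- line_from_y(s$adm_hotspot_y, config)
        row$adm_hotspot_amp <- s$amp_adm
        row$adm_latency <- s$adm_latency
      }
    }

    if (force_level) {
      tr_i <- simulate_force_trace(s$cv_index, config,
                                   seed = substream_seed(seed, "force", i, "index"))
      tr_l <- simulate_force_trace(s$cv_little, config,
                                   seed = substream_seed(seed, "force", i, "little"))
      row$cv_index <- analyze_force_trace(tr_i)$cv
      row$cv_little <- analyze_force_trace(tr_l)$cv
      if (keep_raw) raw$force[[i]] <- list(index = tr_i, little = tr_l)
    } else {
      row$cv_index <- s$cv_index
      row$cv_little <- s$cv_little
    }
    rows[[i]] <- as.data.frame(row)
  }

  tab <- do.call(rbind, rows)
  if (length(r1_na)) {
    tab$r1_caudal[r1_na] <- NA_real_
    tab$r1_rostral[r1_na] <- NA_real_
  }
  tab$r1_mean <- (tab$r1_caudal + tab$r1_rostral) / 2
  line_col <- if ("FDI" %in% muscles) tab$fdi_hotspot_line else tab$adm_hotspot_line
  tab$group <- assign_group(line_col)

  structure(list(table = tab, config = config, grid = grid,
                 subjects = subjects,
                 raw = if (keep_raw) raw else NULL),
            class = "knob_cohort")
}

#' @export
print.knob_cohort <- function(x, ...) {
  tb <- table(x$table$group)
  cat(sprintf("<knob_cohort> %d subjects (%s), %d with R1\n",
              nrow(x$table),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", "),
              sum(is.finite(x$table$r1_mean))))
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' Writes `cohort.csv` (the wide table; the column dictionary is in the
#' cohort-table documentation), `generator_config.txt` (key = value,
#' including the seed) and `manifest.json` (seed, config hash, row count,
#' file list) into `dir`.
#'
#' @param cohort a `knob_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "knob_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  write_generator_config(cohort$config, file.path(dir, "generator_config.txt"))
  cfg_txt <- paste(readLines(file.path(dir, "generator_config.txt")),
                   collapse = "\n")
  manifest <- list(seed = cohort$config$seed,
                   n_subjects = nrow(cohort$table),
                   config_hash = text_hash(cfg_txt),
                   files = c("cohort.csv", "generator_config.txt"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param path path to a `cohort.csv`.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path)
}
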