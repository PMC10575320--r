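#' Default run configuration
#'
#' All model constants and run controls with their defaults (the N = 30
#' study conditions). [load_config()] fills omitted keys from this list and
#' rejects unknown keys by name.
#'
#' @return A named list of class `helix_config`.
#' @export
default_config <- function() {
  structure(list(
    # "n" is a YAML 1.1 boolean scalar (like "y"/"no"), so the chain length
    # key must be spelled out for configs to round-trip through YAML
    n_monomers = 30, t_min = 0.2, t_max = 1.6, n_temp = 16,
    s_tau = seq(5, 14, length.out = 10),
    sweeps = 20000, burn_in = 2000, exchange_interval = 100,
    move_mix = c(local = 0.7, global = 0.1, bend = 0.1, torsion = 0.1),
    local_step = 0.3, global_step = 0.3, max_bend = 0.5, max_torsion = 0.5,
    e_bin = 0.1, q_bin = 0.02,
    s_theta = 200, s_lj = 1, r0 = 1, R = 3 / 7,
    theta0 = 1.742, tau0 = 0.873, lj_bonded = FALSE,
    angle_convention = "bond",
    window = 51, sg_order = 4, zero_fraction = 0.9, prominence = NULL,
    init = "helix", seed = 1, out_dir = "helixmc-out", log_level = "info"
  ), class = "helix_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file of run settings, fills omitted keys with the defaults
#' of [default_config()], and validates the result. Unknown keys are
#' rejected with an error naming the key; configurations round-trip
#' losslessly through [save_config()].
#'
#' @param path a YAML file (an empty file yields all defaults).
#' @return A validated `helix_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(raw)) {
    v <- raw[[k]]
    if (is.null(v)) next # YAML `~` means "use the default"
    if (k == "move_mix") v <- unlist(v)
    cfg[[k]] <- v
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  fail <- function(field, msg) stop("config field `", field, "`: ", msg)
  num_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v <= 0)) fail(field, "must be positive")
  }
  for (f in c("n_monomers", "t_min", "t_max", "n_temp", "s_tau",
              "exchange_interval",
              "local_step", "global_step", "max_bend", "max_torsion",
              "e_bin", "q_bin", "r0", "R", "window")) num_pos(f)
  if (cfg$sweeps <= cfg$burn_in) fail("sweeps", "must exceed burn_in")
  if (cfg$burn_in < 0) fail("burn_in", "must be non-negative")
  if (length(cfg$move_mix) != 4 || any(cfg$move_mix < 0)) {
    fail("move_mix", "must be 4 non-negative weights")
  }
  if (!cfg$angle_convention %in% c("bond", "interior")) {
    fail("angle_convention", 'must be "bond" or "interior"')
  }
  if (cfg$window %% 2 == 0) fail("window", "must be odd")
  class(cfg) <- "helix_config"
  cfg
}

#' @rdname load_config
#' @param cfg a `helix_config` list.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$move_mix <- as.list(out$move_mix)
  atomic_write(path, function(p) yaml::write_yaml(out, p, precision = 15))
  invisible(path)
}

config_params <- function(cfg, s_tau = cfg$s_tau[1]) {
  model_params(s_tau = s_tau, s_theta = cfg$s_theta, s_lj = cfg$s_lj,
               r0 = cfg$r0, R = cfg$R, theta0 = cfg$theta0, tau0 = cfg$tau0,
               lj_bonded = isTRUE(cfg$lj_bonded),
               angle_convention = cfg$angle_convention)
}

config_schedule <- function(cfg) {
  build_schedule(n = cfg$n_monomers, t_range = c(cfg$t_min, cfg$t_max),
                 n_temp = cfg$n_temp, s_tau = cfg$s_tau,
                 sweeps = cfg$sweeps, burn_in = cfg$burn_in,
                 exchange_interval = cfg$exchange_interval,
                 move_mix = cfg$move_mix, local_step = cfg$local_step,
                 global_step = cfg$global_step, max_bend = cfg$max_bend,
                 max_torsion = cfg$max_torsion, e_bin = cfg$e_bin,
                 q_bin = cfg$q_bin, seed = cfg$seed)
}

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Read and write conformations as XYZ
#'
#' One element tag ("C") per monomer; the comment line carries the energy,
#' order parameter, torsion scale and temperature as `key=value` pairs.
#'
#' @param x an `N x 3` coordinate matrix.
#' @param path output file.
#' @param energy,q,s_tau,temperature optional metadata for the comment line.
#' @return `write_xyz` the path, invisibly; `read_xyz` a list with `coords`
#'   and `info` (named numeric metadata).
#' @export
write_xyz <- function(x, path, energy = NA, q = NA, s_tau = NA,
                      temperature = NA) {
  x <- check_conformation(x)
  comment <- sprintf("E=%.10g q=%.10g s_tau=%.10g T=%.10g",
                     energy, q, s_tau, temperature)
  lines <- c(nrow(x), comment,
             sprintf("C %.12g %.12g %.12g", x[, 1], x[, 2], x[, 3]))
  atomic_write(path, function(p) writeLines(lines, p))
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n) || length(lines) < n + 2) stop("malformed XYZ file: ", path)
  info <- lines[2]
  kv <- regmatches(info, gregexpr("[A-Za-z_]+=[-0-9.eE+NnAa]+", info))[[1]]
  vals <- stats::setNames(
    suppressWarnings(as.numeric(sub(".*=", "", kv))), sub("=.*", "", kv))
  coords <- do.call(rbind, lapply(lines[3:(n + 2)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])
  }))
  list(coords = coords, info = vals)
}

header_block <- function(kv) {
  vapply(names(kv), function(k) {
    sprintf("# %s=%s", k, paste(format(kv[[k]], digits = 17), collapse = ","))
  }, character(1))
}

parse_header <- function(lines, required) {
  hl <- grep("^# ", lines, value = TRUE)
  kv <- list()
  for (l in hl) {
    body <- sub("^# ", "", l)
    k <- sub("=.*", "", body)
    kv[[k]] <- as.numeric(strsplit(sub("^[^=]*=", "", body), ",")[[1]])
  }
  miss <- setdiff(required, names(kv))
  if (length(miss)) {
    stop("corrupted table header: missing ", paste(miss, collapse = ", "))
  }
  kv
}

#' Persist histograms as TSV with metadata headers
#'
#' Tab-separated counts with `#`-prefixed metadata lines (`beta`, `s_tau`,
#' `m`, `e_bin`, ...); re-reading reproduces integer counts bitwise and
#' real metadata to full precision.
#'
#' @param h a `helix_histograms` object.
#' @param path output file.
#' @return The path, invisibly (`read_histograms` the object).
#' @export
write_histograms <- function(h, path) {
  hdr <- header_block(list(e_bin = h$e_bin, beta = h$beta,
                           temperature = h$temperature, s_tau = h$s_tau,
                           m = h$m))
  df <- data.frame(e_mid = h$e_mid, h$counts)
  names(df) <- c("e_mid", paste0("thread_", seq_along(h$beta)))
  atomic_write(path, function(p) {
    con <- file(p, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  })
  invisible(path)
}

#' @rdname write_histograms
#' @export
read_histograms <- function(path) {
  lines <- readLines(path)
  kv <- parse_header(lines, c("e_bin", "beta", "m"))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t")
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  structure(list(
    e_mid = df$e_mid, e_bin = kv$e_bin[1], counts = counts,
    beta = kv$beta, temperature = kv$temperature %||% (1 / kv$beta),
    s_tau = kv$s_tau %||% NA_real_, m = kv$m
  ), class = "helix_histograms")
}

#' Persist a density of states as TSV
#'
#' @param dos a `helix_dos` object.
#' @param path output file.
#' @return The path, invisibly (`read_dos` the object).
#' @export
write_dos <- function(dos, path) {
  hdr <- header_block(list(e_bin = dos$e_bin, s_tau = dos$s_tau,
                           gauge = dos$gauge, iterations = dos$iterations,
                           converged = as.numeric(dos$converged),
                           beta = dos$log_z$beta, log_z = dos$log_z$log_z))
  df <- data.frame(E = dos$table$E,
                   log_g = format(dos$table$log_g, digits = 17),
                   support = as.integer(dos$table$support))
  atomic_write(path, function(p) {
    con <- file(p, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  })
  invisible(path)
}

#' @rdname write_dos
#' @export
read_dos <- function(path) {
  lines <- readLines(path)
  kv <- parse_header(lines, c("e_bin", "gauge", "beta", "log_z"))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t")
  new_dos(df$E, as.numeric(df$log_g), df$support == 1, as.integer(kv$gauge[1]),
          log_z = tibble::tibble(beta = kv$beta, temperature = 1 / kv$beta,
                                 log_z = kv$log_z),
          iterations = as.integer(kv$iterations[1] %||% 0),
          converged = isTRUE(kv$converged[1] == 1), e_bin = kv$e_bin[1],
          s_tau = (kv$s_tau %||% NA_real_)[1])
}

#' Run the full analysis pipeline
#'
#' One call reproduces, for each torsion scale in the configuration:
#' replica-exchange sampling, 1D and 2D histograms, the WHAM density of
#' states, smoothed entropy curves, the transition report, the structural
#' prevalence field, and canonical mean-energy / specific-heat tables. When
#' `out_dir` is given every artifact is persisted (TSV/JSON/XYZ) together
#' with a JSON manifest recording the configuration hash, seed and package
#' version. A failing stage aborts with the stage name; the manifest lists
#' the stages that completed.
#'
#' @param cfg a `helix_config` list (see [default_config()]).
#' @param out_dir output directory (`NULL` to skip persistence).
#' @param progress print stage messages?
#' @return A list per `s_tau` value with elements `dos`, `dos2d`, `curves`,
#'   `transitions`, `prevalence`, `canonical`, plus `run` (the sampler
#'   output) and `manifest`.
#' @export
pipeline_run <- function(cfg = default_config(), out_dir = cfg$out_dir,
                         progress = FALSE) {
  cfg <- validate_config(cfg)
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  stages <- character()
  stage <- function(name, expr) {
    if (progress) message("stage: ", name)
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           "\ncompleted stages: ", paste(stages, collapse = ", "),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }
  emit <- function(obj, fname, writer) {
    if (!persist) return(invisible(NULL))
    p <- file.path(out_dir, fname)
    writer(obj, p)
    files <<- c(files, fname)
  }

  schedule <- config_schedule(cfg)
  params <- config_params(cfg)
  run <- stage("simulate", run_grid(schedule, params, init = cfg$init,
                                    seed = cfg$seed))
  results <- list()
  for (s in cfg$s_tau) {
    tag <- gsub("[^0-9a-zA-Z.]", "_", format(s))
    h1 <- stage(paste0("histograms[", tag, "]"),
                energy_histograms(run, s_tau = s))
    h2 <- joint_histograms(run, s_tau = s)
    emit(h1, sprintf("hist_s%s.tsv", tag), write_histograms)
    dos <- stage(paste0("reweight[", tag, "]"), wham(h1))
    emit(dos, sprintf("dos_s%s.tsv", tag), write_dos)
    dos2d <- stage(paste0("reweight2d[", tag, "]"), wham_2d(h2, dos))
    curves <- stage(paste0("analyze[", tag, "]"), {
      sc <- entropy_from_dos(dos)
      smooth_derivatives(sc, window = cfg$window, order = cfg$sg_order)
    })
    emit(curves, sprintf("curves_s%s.tsv", tag), function(o, p) {
      atomic_write(p, function(pp) {
        utils::write.table(as.data.frame(o), pp, sep = "\t",
                           row.names = FALSE, quote = FALSE)
      })
    })
    trans <- detect_transitions(curves, prominence = cfg$prominence,
                                zero_fraction = cfg$zero_fraction)
    emit(trans, sprintf("transitions_s%s.json", tag), function(o, p) {
      atomic_write(p, function(pp) {
        jsonlite::write_json(as.data.frame(o), pp, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
      })
    })
    prev <- stage(paste0("prevalence[", tag, "]"), prevalence_field(dos2d))
    emit(prev, sprintf("prevalence_s%s.tsv", tag), function(o, p) {
      atomic_write(p, function(pp) {
        utils::write.table(as.data.frame(o), pp, sep = "\t",
                           row.names = FALSE, quote = FALSE)
      })
    })
    canonical <- canonical_observables(
      dos, seq(cfg$t_min, cfg$t_max, length.out = 200))
    emit(canonical, sprintf("canonical_s%s.tsv", tag), function(o, p) {
      atomic_write(p, function(pp) {
        utils::write.table(as.data.frame(o), pp, sep = "\t",
                           row.names = FALSE, quote = FALSE)
      })
    })
    best <- which(abs(run$minima$s_tau - s) < 1e-9)
    bt <- best[which.min(run$minima$min_energy[best])]
    if (!is.null(run$min_coords[[bt]])) {
      emit(run$min_coords[[bt]], sprintf("min_s%s.xyz", tag), function(o, p) {
        write_xyz(o, p, energy = run$minima$min_energy[bt],
                  q = run$minima$min_q[bt], s_tau = s,
                  temperature = run$minima$temperature[bt])
      })
    }
    results[[paste0("s_tau_", tag)]] <- list(
      s_tau = s, histograms = h1, dos = dos, dos2d = dos2d, curves = curves,
      transitions = trans, prevalence = prev, canonical = canonical)
  }
  manifest <- list(
    package = "helixmc",
    version = as.character(utils::packageVersion("helixmc")),
    seed = cfg$seed, config_hash = rlang::hash(unclass(cfg)),
    stages = stages, files = files
  )
  if (persist) {
    atomic_write(file.path(out_dir, "manifest.json"), function(p) {
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
    })
  }
  structure(list(run = run, results = results, manifest = manifest,
                 config = cfg), class = "helix_pipeline")
}
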