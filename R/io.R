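# Strict tabular/JSON I/O and the command-line dispatcher binding the
# pipeline stages together.

# read a CSV with header validation and located parse errors
.read_strict_csv <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
  for (col in setdiff(required, "age_group")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop(sprintf("malformed numeric in column '%s' of %s at row %s",
                     col, path, paste(bad, collapse = ", ")))
      df[[col]] <- num
    }
  }
  df
}

#' Read / write a JSON run configuration
#'
#' Plain JSON objects; used for homeostasis-specification and grid
#' overrides in the command-line pipeline.
#'
#' @param path JSON file path.
#' @return `read_json_config`: a named list. `write_json_config`:
#'   `path`, invisibly.
#' @export
read_json_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_json_config
#' @param config Named list to serialise.
#' @export
write_json_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# homeostasis_spec from a config list (NULL fields fall back to defaults)
.spec_from_config <- function(cfg) {
  args <- cfg[intersect(names(cfg),
                        c("sigma_setpoint", "p_operating", "weights",
                          "k3_over_k1", "lambda_z", "p_tlc",
                          "yinc_pressures", "tol_stress",
                          "tol_yinc_log"))]
  if (!is.null(cfg$yinc_reference_csv))
    args$yinc_reference <- utils::read.csv(cfg$yinc_reference_csv)
  do.call(homeostasis_spec, args)
}

.grid_from_config <- function(cfg, axes = c("k1", "k2")) {
  g <- cfg$grid
  if (is.null(g)) return(NULL)
  lower <- if (!is.null(g$lower)) stats::setNames(as.numeric(g$lower), axes)
  upper <- if (!is.null(g$upper)) stats::setNames(as.numeric(g$upper), axes)
  args <- list(n = g$n %||% 12L, refine = g$refine %||% 2L,
               shrink = g$shrink %||% 5)
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  if (is.null(lower) && length(axes) == 2L) {
    args$lower <- c(k1 = 0.02, k2 = 0.05)
    args$upper <- c(k1 = 50, k2 = 60)
  }
  do.call(grid_spec, args)
}

.cli_parse <- function(args) {
  if (!length(args)) stop("usage: airwaymech <subcommand> [--flags]")
  out <- list(subcommand = args[[1]], flags = list())
  i <- 2L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (key == "force") { out$flags$force <- TRUE; i <- i + 1L; next }
    if (i + 1L > length(args)) stop("flag ", a, " needs a value")
    out$flags[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

.cli_prepare_out <- function(flags) {
  out_dir <- flags$out %||% "."
  if (dir.exists(out_dir) && length(list.files(out_dir)) &&
      !isTRUE(flags$force))
    stop("output directory ", out_dir,
         " is not empty; pass --force to overwrite")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

.cli_log <- function(out_dir, subcommand, flags, cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(flags = flags, config = cfg), tmp,
                       auto_unbox = TRUE, digits = NA)
  log <- list(subcommand = subcommand,
              config_hash = unname(tools::md5sum(tmp)),
              seed = as.integer(flags$seed %||% 1L),
              package_version = as.character(utils::packageVersion("airwaymech")),
              r_version = paste(R.version$major, R.version$minor, sep = "."))
  write_json_config(log, file.path(out_dir, "run_log.json"))
}

#' Command-line pipeline dispatcher
#'
#' Implements the subcommands `simulate` (write a synthetic fixture
#' bundle), `fit` (fit one curve CSV), `calibrate-tree` (calibrate a
#' dimension table), `predict` (calibrate and emit tree-wide
#' predictions), `grow` (growth trajectory of one generation) and
#' `remodel` (chronic-constriction remodeling sweep). Flags: `--config
#' PATH` (JSON overrides), `--seed INT`, `--out DIR`, `--force`,
#' `--input PATH`, `--operating-pressure {0.75|0.5}`, `--constriction
#' FLOAT`, `--generation INT`, `--max-generation INT`. Each run writes
#' its artifacts plus a `run_log.json` capturing the config hash and
#' seed.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   the process's trailing arguments).
#' @return Integer exit status, invisibly: 0 on success, 1 on error.
#' @export
airwaymech_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    parsed <- .cli_parse(args)
    flags <- parsed$flags
    cfg <- if (!is.null(flags$config)) read_json_config(flags$config)
           else list()
    if (!is.null(flags$`operating-pressure`))
      cfg$p_operating <- as.numeric(flags$`operating-pressure`)
    seed <- as.integer(flags$seed %||% cfg$seed %||% 1L)
    out_dir <- .cli_prepare_out(flags)

    switch(parsed$subcommand,
      simulate = {
        make_fixture_bundle(out_dir, seed = seed,
                            noise_sd = cfg$noise_sd %||% 0.005)
      },
      fit = {
        if (is.null(flags$input)) stop("fit needs --input <curve.csv>")
        curve <- read_pressure_radius_csv(flags$input,
                                          lambda_z = cfg$lambda_z %||% NULL)
        grid <- .grid_from_config(cfg, c("k1", "k2", "k3")) %||% grid_spec()
        fit <- airway_fit(curve, grid)
        res <- data.frame(label = attr(fit$curve, "label"),
                          k1 = fit$params$k1, k2 = fit$params$k2,
                          k3 = fit$params$k3, sse = fit$sse,
                          rmse = fit$rmse,
                          r_in_ref = fit$ref$r_in, r_out_ref = fit$ref$r_out,
                          boundary = fit$diagnostics$boundary)
        utils::write.csv(res, file.path(out_dir, "fit_result.csv"),
                         row.names = FALSE, quote = FALSE)
        write_json_config(c(as.list(res),
                            fit$diagnostics[c("n_eval", "n_fail",
                                              "dropped_negative")]),
                          file.path(out_dir, "fit_result.json"))
      },
      `calibrate-tree` = ,
      predict = {
        if (is.null(flags$input)) stop(parsed$subcommand,
                                       " needs --input <dimensions.csv>")
        tbl <- read_dimension_csv(flags$input)
        if (!is.null(flags$`max-generation`))
          tbl <- tbl[tbl$generation <=
                       as.integer(flags$`max-generation`), , drop = FALSE]
        spec <- .spec_from_config(cfg)
        tree <- calibrate_tree(tbl, spec, .grid_from_config(cfg))
        s <- summary(tree)
        utils::write.csv(s, file.path(out_dir, "calibrated_params.csv"),
                         row.names = FALSE, quote = FALSE)
        if (parsed$subcommand == "predict") {
          pr <- predict(tree)
          utils::write.csv(pr$summary,
                           file.path(out_dir, "tree_predictions.csv"),
                           row.names = FALSE, quote = FALSE)
          utils::write.csv(pr$curves,
                           file.path(out_dir, "stretch_pressure_curves.csv"),
                           row.names = FALSE, quote = FALSE)
        }
      },
      grow = ,
      remodel = {
        if (is.null(flags$input))
          stop(parsed$subcommand,
               " needs --input <dir with tree_<age>.csv tables>")
        tables <- lapply(c(newborn = "newborn", child = "child",
                           adult = "adult"), function(ag)
          read_dimension_csv(file.path(flags$input,
                                       sprintf("tree_%s.csv", ag))))
        if (!is.null(flags$`max-generation`))
          tables <- lapply(tables, function(t)
            t[t$generation <= as.integer(flags$`max-generation`), ,
              drop = FALSE])
        spec <- .spec_from_config(cfg)
        tree <- calibrate_tree(tables$adult, spec, .grid_from_config(cfg))
        law <- fit_growth_law(tree)
        gen <- as.integer(flags$generation %||% 0L)
        if (parsed$subcommand == "grow") {
          traj <- growth_trajectory(gen, tables, law, spec)
          utils::write.csv(traj,
                           file.path(out_dir, "growth_trajectory.csv"),
                           row.names = FALSE, quote = FALSE)
        } else {
          levels <- if (!is.null(flags$constriction))
            as.numeric(flags$constriction)
          else seq(0.02, 0.1, by = 0.02)
          aw <- tree$airways[[gen + 1L]]
          rows <- lapply(levels, function(cl) {
            r <- chronic_constriction_remodel(aw, cl, law, spec)
            data.frame(constriction = cl, wall_area_mm2 = r$wall_area,
                       d_wall_area = r$d_wall_area,
                       d_compliance = r$d_compliance,
                       sigma_restored_kpa = r$sigma_restored)
          })
          utils::write.csv(do.call(rbind, rows),
                           file.path(out_dir, "remodeling.csv"),
                           row.names = FALSE, quote = FALSE)
        }
      },
      stop("unknown subcommand: ", parsed$subcommand,
           " (expected simulate, fit, calibrate-tree, predict, grow, remodel)")
    )
    .cli_log(out_dir, parsed$subcommand, flags, cfg)
    0L
  }, error = function(e) {
    message("airwaymech error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
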