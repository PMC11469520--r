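#' Load a run configuration from YAML
#'
#' The file mirrors the module configs in sections `predictor`, `extraction`,
#' `screening`, `rl`, `synth`, plus top-level `log_level` and `output_dir`.
#' Unknown sections or keys are rejected so typos cannot silently fall back
#' to defaults. Every omitted key takes the documented default of the
#' corresponding constructor.
#'
#' @param path YAML file path (NULL gives all defaults).
#' @return A `run_config` list with fully-resolved module configs.
#' @export
load_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("predictor", "extraction", "screening", "rl", "synth",
             "log_level", "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) stop("unknown config section(s): ",
                            paste(bad, collapse = ", "))
  take <- function(section, fn, extra_ok = character()) {
    args <- raw[[section]] %||% list()
    ok <- c(names(formals(fn)), extra_ok)
    bad <- setdiff(names(args), ok)
    if (length(bad) > 0) stop("unknown key(s) in config section '", section,
                              "': ", paste(bad, collapse = ", "))
    args
  }
  pa <- take("predictor", predictor_config)
  ea <- take("extraction", extraction_config)
  ra <- take("rl", q_train_config, extra_ok = c("eps0", "eps_final", "alpha",
                                                "delta_ff", "delta_fp"))
  sa <- take("synth", synthetic_pocket_spec,
             extra_ok = c("n_actives", "n_decoys", "jitter_sigma",
                          "decoy_mode", "n_features"))
  sc <- raw[["screening"]] %||% list()
  bad <- setdiff(names(sc), c("exclusion", "r_excl", "cap"))
  if (length(bad) > 0) stop("unknown key(s) in config section 'screening': ",
                            paste(bad, collapse = ", "))
  sched <- epsilon_schedule(ra$eps0 %||% 0.9, ra$eps_final %||% 0.05,
                            ra$alpha %||% 100)
  thr <- graph_thresholds(ra$delta_ff %||% 8.0, ra$delta_fp %||% 5.0)
  ra[c("eps0", "eps_final", "alpha", "delta_ff", "delta_fp")] <- NULL
  ra$schedule <- sched
  structure(list(
    predictor = do.call(predictor_config, pa),
    extraction = do.call(extraction_config, ea),
    screening = sc,
    rl = do.call(q_train_config, ra),
    thresholds = thr,
    synth = sa,
    log_level = raw$log_level %||% "info",
    output_dir = raw$output_dir %||% "."
  ), class = "run_config")
}

log_line <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(...)))
}

cli_usage <- function() {
  paste(
    "usage: apopharm <command> [options]",
    "",
    "commands:",
    "  simulate pocket|library|task  --out DIR [--seed N] [--config cfg.yaml]",
    "  extract-features  --protein in.pdb --model ckpt.json",
    "                    (--box x1,y1,z1,x2,y2,z2 | --ligand feats.json [--pad 4.0])",
    "                    --out features.json",
    "  screen            --pharm p.json --library lib.jsonl",
    "                    [--protein rec.pdb --exclusion] [--out result.json]",
    "  enumerate-baseline --features f.json --library lib.jsonl [--cap N] --out out.json",
    "  train-cnn         --protein rec.pdb --samples s.jsonl --out ckpt.json [--seed N]",
    "  train-q           --features f.json --protein rec.pdb --library lib.jsonl",
    "                    [--config cfg.yaml] [--seed N] --out DIR",
    "  build-pharmacophore --ensemble DIR --features f.json --protein rec.pdb",
    "                    [--library lib.jsonl] [--min-features 3|4] [--top-k 2] --out DIR",
    "",
    "global flags: --config FILE, --seed N, --version",
    sep = "\n")
}

parse_cli <- function(argv) {
  flags <- list(); positional <- character()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (a %in% c("--exclusion", "--version")) {
      flags[[sub("^--", "", a)]] <- TRUE
      i <- i + 1
    } else if (grepl("^--", a)) {
      if (i == length(argv)) stop("flag ", a, " needs a value")
      flags[[sub("^--", "", a)]] <- argv[i + 1]
      i <- i + 2
    } else {
      positional <- c(positional, a)
      i <- i + 1
    }
  }
  list(flags = flags, positional = positional)
}

need_flag <- function(p, name) {
  v <- p$flags[[name]]
  if (is.null(v)) stop("missing required flag --", name)
  v
}

cli_box <- function(p, cfg) {
  if (!is.null(p$flags$box)) {
    v <- as.numeric(strsplit(p$flags$box, ",")[[1]])
    if (length(v) != 6 || any(is.na(v))) stop("--box needs x1,y1,z1,x2,y2,z2")
    box3(pmin(v[1:3], v[4:6]), pmax(v[1:3], v[4:6]))
  } else if (!is.null(p$flags$ligand)) {
    box_around(read_features(p$flags$ligand),
               pad = as.numeric(p$flags$pad %||% 4.0))
  } else stop("supply --box or --ligand")
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `apopharm` command-line tool (see
#' `inst/cli/apopharm`). Returns an exit code rather than quitting, so it is
#' callable in-process.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code: 0 success, 1 runtime failure, 2 usage error.
#' @export
main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage_fail <- function(msg) {
    message(msg)
    message(cli_usage())
    2L
  }
  if (length(argv) == 0) return(usage_fail("no command given"))
  p <- tryCatch(parse_cli(argv), error = function(e) e)
  if (inherits(p, "error")) return(usage_fail(conditionMessage(p)))
  if (isTRUE(p$flags$version)) {
    message("apopharm ", as.character(utils::packageVersion("apopharm")))
    return(0L)
  }
  if (length(p$positional) == 0) return(usage_fail("no command given"))
  cmd <- p$positional[1]
  cmds <- c("simulate", "extract-features", "screen", "enumerate-baseline",
            "train-cnn", "train-q", "build-pharmacophore")
  if (!cmd %in% cmds) return(usage_fail(paste0("unknown command: ", cmd)))
  run <- function() {
    cfg <- load_run_config(p$flags$config)
    seed <- as.integer(p$flags$seed %||% 1L)
    switch(cmd,
      "simulate" = cli_simulate(p, cfg, seed),
      "extract-features" = cli_extract(p, cfg),
      "screen" = cli_screen(p, cfg),
      "enumerate-baseline" = cli_enumerate(p, cfg, seed),
      "train-cnn" = cli_train_cnn(p, cfg, seed),
      "train-q" = cli_train_q(p, cfg, seed),
      "build-pharmacophore" = cli_build(p, cfg))
    0L
  }
  tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}

cli_simulate <- function(p, cfg, seed) {
  what <- p$positional[2]
  if (is.na(what) || !what %in% c("pocket", "library", "task")) {
    stop("simulate needs one of: pocket, library, task")
  }
  out <- need_flag(p, "out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sa <- cfg$synth
  if (what == "pocket") {
    spec_args <- sa[intersect(names(sa), names(formals(synthetic_pocket_spec)))]
    spec_args$seed <- seed
    pocket <- make_pocket(do.call(synthetic_pocket_spec, spec_args))
    write_pdb(pocket$protein, file.path(out, "pocket.pdb"))
    write_features(pocket$truth, file.path(out, "truth_features.json"))
    write_predictor(pocket$predictor, file.path(out, "oracle_model.json"))
    log_line("simulate", "pocket with ", nrow(pocket$truth),
             " planted sites -> ", out)
  } else if (what == "library") {
    pocket <- make_pocket(synthetic_pocket_spec(seed = seed))
    planted <- pharmacophore(pocket$truth[seq_len(min(4, nrow(pocket$truth))), ],
                             "planted")
    lib <- make_library(synthetic_library_spec(
      planted, n_actives = as.integer(sa$n_actives %||% 20),
      n_decoys = as.integer(sa$n_decoys %||% 80),
      jitter_sigma = as.numeric(sa$jitter_sigma %||% 0.3),
      decoy_mode = sa$decoy_mode %||% "perturb_geometry", seed = seed))
    write_pharmacophore(planted, file.path(out, "planted.json"))
    write_library(lib, file.path(out, "library.jsonl"))
    log_line("simulate", length(lib), " molecules -> ", out)
  } else {
    task <- make_unique_optimum_task(
      n_features = as.integer(sa$n_features %||% 8), seed = seed)
    write_pdb(task$protein, file.path(out, "protein.pdb"))
    write_features(task$features, file.path(out, "features.json"))
    write_library(task$library, file.path(out, "library.jsonl"))
    jsonlite::write_json(list(optimal = task$optimal, seed = task$seed),
                         file.path(out, "task.json"), auto_unbox = TRUE)
    log_line("simulate", "unique-optimum task (optimal subset ",
             paste(task$optimal, collapse = "+"), ") -> ", out)
  }
}

cli_extract <- function(p, cfg) {
  protein <- load_protein(need_flag(p, "protein"))
  model <- read_predictor(need_flag(p, "model"))
  box <- cli_box(p, cfg)
  feats <- extract_features(model, protein, box, cfg$extraction)
  write_features(feats, need_flag(p, "out"))
  log_line("extract-features", nrow(feats), " features -> ", p$flags$out)
}

cli_screen <- function(p, cfg) {
  pharm <- read_pharmacophore(need_flag(p, "pharm"))
  lib <- read_library(need_flag(p, "library"))
  opts <- cfg$screening
  if (isTRUE(p$flags$exclusion)) {
    opts$exclusion <- TRUE
    opts$protein <- load_protein(need_flag(p, "protein"))
  }
  res <- screen_library(pharm, lib, opts)
  g <- glance(res)
  log_line("screen", sprintf("F1 %.3f EF %.2f (tp %d fp %d fn %d tn %d)",
                             g$f1, g$enrichment_factor, g$tp, g$fp, g$fn, g$tn))
  if (!is.null(p$flags$out)) {
    jsonlite::write_json(as.list(g), p$flags$out, auto_unbox = TRUE,
                         digits = NA)
  }
}

cli_enumerate <- function(p, cfg, seed) {
  feats <- read_features(need_flag(p, "features"))
  lib <- read_library(need_flag(p, "library"))
  enum <- enumerate_baseline(feats, lib,
                             cap = as.integer(p$flags$cap %||% 10000L),
                             seed = seed, options = cfg$screening)
  log_line("enumerate-baseline",
           sprintf("best F1 %.3f mean F1 %.3f over %d subsets",
                   enum$best_f1, enum$mean_f1, enum$n_evaluated))
  jsonlite::write_json(list(best_f1 = enum$best_f1, mean_f1 = enum$mean_f1,
                            n_evaluated = enum$n_evaluated,
                            best_subset = enum$results$subset[
                              which.max(enum$results$f1)]),
                       need_flag(p, "out"), auto_unbox = TRUE, digits = NA)
}

cli_train_cnn <- function(p, cfg, seed) {
  protein <- load_protein(need_flag(p, "protein"))
  lines <- readLines(need_flag(p, "samples"), warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  samples <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    training_sample(protein, as.numeric(obj$point), as.numeric(obj$labels),
                    is_adversarial = isTRUE(obj$is_adversarial))
  })
  model <- train_predictor(samples, cfg$predictor, seed = seed)
  write_predictor(model, need_flag(p, "out"))
  log_line("train-cnn", length(samples), " samples, final loss ",
           sprintf("%.4f", utils::tail(model$trace, 1)), " -> ", p$flags$out)
}

cli_train_q <- function(p, cfg, seed) {
  feats <- read_features(need_flag(p, "features"))
  protein <- load_protein(need_flag(p, "protein"))
  lib <- read_library(need_flag(p, "library"))
  env <- make_env(feats, protein, library = lib, thresholds = cfg$thresholds,
                  min_features = cfg$rl$min_features, options = cfg$screening)
  qc <- cfg$rl
  qc$seed <- as.integer(seed)
  ensemble <- train_q(env, qc)
  out <- need_flag(p, "out")
  write_ensemble(ensemble, out)
  log_line("train-q", length(ensemble$members), " members x ",
           qc$episodes, " episodes -> ", out)
}

cli_build <- function(p, cfg) {
  ensemble <- read_ensemble(need_flag(p, "ensemble"))
  feats <- read_features(need_flag(p, "features"))
  protein <- load_protein(need_flag(p, "protein"))
  lib <- if (!is.null(p$flags$library)) read_library(p$flags$library) else NULL
  opts <- cfg$screening
  opts$min_features <- as.integer(p$flags[["min-features"]] %||%
                                    ensemble$config$min_features)
  opts$top_k <- as.integer(p$flags[["top-k"]] %||% 2L)
  opts$thresholds <- cfg$thresholds
  ranked <- build_pharmacophore(ensemble, feats, protein, library = lib,
                                options = opts)
  out <- need_flag(p, "out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(ranked))) {
    write_pharmacophore(ranked$pharm[[i]],
                        file.path(out, sprintf("rank_%02d.json", i)))
  }
  jsonlite::write_json(
    lapply(seq_len(nrow(ranked)), function(i) {
      list(rank = ranked$rank[i], subset = ranked$subset[i],
           size = ranked$size[i], score = ranked$score[i], q = ranked$q[i])
    }),
    file.path(out, "ranking.json"), auto_unbox = TRUE, digits = NA)
  log_line("build-pharmacophore", nrow(ranked), " ranked pharmacophores -> ",
           out)
}
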