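# Self-describing JSON checkpoints (config + weights) for predictors and
# Q-ensembles. JSON keeps checkpoints portable and diffable; these nets are
# small enough that text weights are cheap.

net_to_json <- function(net) {
  list(sizes = net$sizes,
       W = lapply(net$W, function(w) apply(w, 1, identity, simplify = FALSE)),
       b = net$b)
}

net_from_json <- function(obj) {
  sizes <- as.integer(unlist(obj$sizes))
  # weights are stored row-per-entry
  W <- lapply(obj$W, function(rows) do.call(rbind, lapply(rows, as.numeric)))
  structure(list(sizes = sizes, W = W,
                 b = lapply(obj$b, as.numeric)),
            class = "dense_net")
}

#' Save a predictor model checkpoint
#'
#' @param model A [site_predictor()] or [oracle_predictor()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_predictor <- function(model, path) {
  obj <- if (inherits(model, "site_predictor")) {
    list(type = "site_predictor",
         config = unclass(model$config),
         net = net_to_json(model$net),
         trace = model$trace)
  } else if (inherits(model, "oracle_predictor")) {
    list(type = "oracle_predictor",
         sites = model$sites, blob_sigma = model$blob_sigma,
         noise_level = model$noise_level,
         embedding_size = model$embedding_size,
         noise_freq = apply(model$noise_freq, 1, identity, simplify = FALSE),
         noise_phase = model$noise_phase,
         emb_W = apply(model$emb_W, 1, identity, simplify = FALSE),
         emb_b = model$emb_b)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a predictor model checkpoint
#'
#' @param path JSON checkpoint from [write_predictor()].
#' @return The restored model.
#' @export
read_predictor <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(obj$type, "site_predictor")) {
    cfgl <- obj$config
    config <- predictor_config(
      box_edge = cfgl$box_edge, resolution = cfgl$resolution,
      channels = unlist(cfgl$channels),
      embedding_size = cfgl$embedding_size,
      gaussian_width_scale = cfgl$gaussian_width_scale,
      hidden = cfgl$hidden, pool = cfgl$pool)
    model <- site_predictor(config)
    model$net <- net_from_json(obj$net)
    model$trace <- if (is.null(obj$trace)) NULL else as.numeric(unlist(obj$trace))
    model
  } else if (identical(obj$type, "oracle_predictor")) {
    sites <- dplyr::bind_rows(lapply(obj$sites, tibble::as_tibble))
    m <- oracle_predictor(sites, blob_sigma = obj$blob_sigma,
                          noise_level = obj$noise_level,
                          embedding_size = obj$embedding_size)
    m$noise_freq <- do.call(rbind, lapply(obj$noise_freq, as.numeric))
    m$noise_phase <- as.numeric(unlist(obj$noise_phase))
    m$emb_W <- do.call(rbind, lapply(obj$emb_W, as.numeric))
    m$emb_b <- as.numeric(unlist(obj$emb_b))
    m
  } else stop("unknown checkpoint type: ", obj$type)
}

#' Save a trained Q-ensemble to a directory
#'
#' Writes one self-describing JSON per member plus the shared config.
#'
#' @param ensemble A `q_ensemble` from [train_q()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- ensemble$config
  cfg$schedule <- unclass(cfg$schedule)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (m in seq_along(ensemble$members)) {
    mem <- ensemble$members[[m]]
    jsonlite::write_json(
      list(embedding_size = mem$network$embedding_size,
           net = net_to_json(mem$network$net)),
      file.path(dir, sprintf("member_%d.json", m)),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(mem$trace,
                     file.path(dir, sprintf("trace_%d.csv", m)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a Q-ensemble directory written by [write_ensemble()]
#'
#' @param dir Ensemble directory.
#' @return A `q_ensemble`.
#' @export
read_ensemble <- function(dir) {
  cfgl <- jsonlite::fromJSON(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  sched <- epsilon_schedule(cfgl$schedule$eps0, cfgl$schedule$eps_final,
                            cfgl$schedule$alpha)
  config <- q_train_config(
    gamma = cfgl$gamma, min_features = cfgl$min_features,
    episodes = cfgl$episodes, ensemble_size = cfgl$ensemble_size,
    schedule = sched, replay_capacity = cfgl$replay_capacity,
    batch_size = cfgl$batch_size, learning_rate = cfgl$learning_rate,
    target_sync_every = cfgl$target_sync_every,
    updates_per_step = cfgl$updates_per_step,
    hidden = cfgl$hidden, seed = cfgl$seed)
  files <- sort(list.files(dir, pattern = "^member_\\d+\\.json$",
                           full.names = TRUE))
  members <- lapply(files, function(f) {
    obj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
    network <- structure(
      list(net = net_from_json(obj$net),
           embedding_size = as.integer(obj$embedding_size)),
      class = "q_network")
    tracef <- sub("member_(\\d+)\\.json$", "trace_\\1.csv", f)
    trace <- if (file.exists(tracef)) {
      tibble::as_tibble(utils::read.csv(tracef))
    } else NULL
    list(network = network, trace = trace)
  })
  structure(list(members = members, config = config), class = "q_ensemble")
}
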