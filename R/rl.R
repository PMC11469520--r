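#' Exponentially decaying exploration schedule
#'
#' `epsilon(t) = eps_final + (eps0 - eps_final) * exp(-t / alpha)`: early
#' episodes explore (random legal actions), later episodes exploit the
#' learned value function.
#'
#' @param eps0 Initial exploration probability (default 0.9).
#' @param eps_final Asymptotic exploration probability (default 0.05).
#' @param alpha Decay rate in episodes (default 100).
#' @export
epsilon_schedule <- function(eps0 = 0.9, eps_final = 0.05, alpha = 100) {
  if (!(eps_final >= 0 && eps_final <= eps0 && eps0 <= 1)) {
    stop("need 0 <= eps_final <= eps0 <= 1")
  }
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(eps0 = eps0, eps_final = eps_final, alpha = alpha),
            class = "epsilon_schedule")
}

#' Exploration probability at episode t
#'
#' @param schedule An [epsilon_schedule()].
#' @param t Episode counter (>= 0).
#' @return `eps_final + (eps0 - eps_final) * exp(-t / alpha)`.
#' @export
epsilon_at <- function(schedule, t) {
  stopifnot(all(t >= 0))
  schedule$eps_final + (schedule$eps0 - schedule$eps_final) * exp(-t / schedule$alpha)
}

#' Create a pharmacophore-assembly environment
#'
#' Wraps a candidate feature set, protein and reward oracle into the MDP the
#' Q-learning agent interacts with. The default reward of a graph is the F1
#' score of screening `library` with the graph's pharmacophore, gated to 0
#' below `min_features`; any function `graph -> numeric` can replace it.
#' Rewards and graph descriptors are memoized per feature subset.
#'
#' @param features Candidate [pharm_features()] (with embeddings).
#' @param protein A [protein_structure()].
#' @param library Molecule library for the screening reward (or NULL if
#'   `reward_fn` is given).
#' @param reward_fn Optional reward oracle, a function of a `pharm_graph`.
#' @param thresholds A [graph_thresholds()].
#' @param min_features Minimum size for termination and non-zero reward.
#' @param options Matcher options passed to [screen_library()].
#' @return A `pharm_env`.
#' @export
make_env <- function(features, protein, library = NULL, reward_fn = NULL,
                     thresholds = graph_thresholds(), min_features = 3L,
                     options = list()) {
  if (min_features < 3) stop("min_features must be >= 3")
  if (is.null(reward_fn)) {
    if (is.null(library)) stop("supply a library or a reward_fn")
    reward_fn <- function(graph) {
      screen_library(graph_pharmacophore(graph), library, options)$metrics$f1
    }
  }
  env <- new.env(parent = emptyenv())
  env$features <- features
  env$protein <- protein
  env$thresholds <- thresholds
  env$min_features <- as.integer(min_features)
  env$reward_fn <- reward_fn
  env$reward_cache <- new.env(parent = emptyenv())
  env$desc_cache <- new.env(parent = emptyenv())
  class(env) <- "pharm_env"
  env
}

env_graph <- function(env, selected) {
  build_graph(selected, env$features, env$protein, env$thresholds)
}

env_reward <- function(env, graph) {
  if (nrow(graph$features) < env$min_features) return(0)
  key <- subset_key(graph$subset)
  if (!is.null(env$reward_cache[[key]])) return(env$reward_cache[[key]])
  r <- as.numeric(env$reward_fn(graph))
  env$reward_cache[[key]] <- r
  r
}

env_descriptor <- function(env, graph, embedding_size) {
  key <- subset_key(graph$subset)
  d <- env$desc_cache[[key]]
  if (is.null(d)) {
    d <- graph_descriptor(graph, embedding_size)
    env$desc_cache[[key]] <- d
  }
  d
}

env_propose <- function(env, state) {
  propose(state, env$features, env$protein, env$thresholds, env$min_features)
}

#' Take one MDP step
#'
#' `action = 0` selects the current graph (terminal; only legal once the
#' graph has `min_features` nodes); `action = k` moves to the k-th candidate
#' graph. The reward is the screening F1 of the resulting graph, 0 below
#' `min_features`.
#'
#' @param env A `pharm_env`.
#' @param state Current `pharm_graph`.
#' @param action Integer action (0 = terminal) indexing the current
#'   proposal set.
#' @param proposals Optional precomputed [propose()] result for `state`.
#' @return A `transition`: `state`, `action_graph`, `reward`,
#'   `next_proposals`, `done`, `dead_end`.
#' @export
step_env <- function(env, state, action, proposals = NULL) {
  if (is.null(proposals)) proposals <- env_propose(env, state)
  if (action == 0) {
    if (!proposals$terminal_allowed) {
      stop("invalid action: terminal not allowed below ", env$min_features,
           " features")
    }
    action_graph <- state
    done <- TRUE
  } else {
    if (action < 0 || action > length(proposals$candidates)) {
      stop("invalid action index ", action)
    }
    action_graph <- proposals$candidates[[action]]
    done <- FALSE
  }
  np <- env_propose(env, action_graph)
  dead_end <- !done && np$dead_end
  structure(list(state = state, action_graph = action_graph,
                 reward = env_reward(env, action_graph),
                 next_proposals = np, done = done, dead_end = dead_end),
            class = "transition")
}

# legal action values under a network: candidates then (optionally) terminal.
# Returns list(actions, values): actions[k] is 0 for terminal.
action_values <- function(env, network, proposals) {
  acts <- seq_along(proposals$candidates)
  descs <- lapply(proposals$candidates, env_descriptor, env = env,
                  embedding_size = network$embedding_size)
  if (proposals$terminal_allowed) {
    acts <- c(acts, 0L)
    descs <- c(descs, list(env_descriptor(env, proposals$current,
                                          network$embedding_size)))
  }
  vals <- if (length(descs)) q_values_mat(network, do.call(rbind, descs)) else numeric(0)
  list(actions = acts, values = vals)
}

#' Simulate one epsilon-greedy episode
#'
#' Starts from a single-feature seed graph (sampled uniformly unless
#' `seed_feature` is given), then repeatedly either explores a uniformly
#' random legal action (probability `epsilon`) or takes the Q-greedy action
#' over the candidate graphs and the terminal option. Ends on terminal,
#' dead end, or `max_steps`.
#'
#' @param env A `pharm_env`.
#' @param network A [q_network()].
#' @param epsilon Exploration probability in \[0,1\].
#' @param seed_feature Optional index of the seed feature.
#' @param max_steps Cap on episode length (default: number of features + 1).
#' @return List of `transition` objects.
#' @export
run_episode <- function(env, network, epsilon, seed_feature = NULL,
                        max_steps = NULL) {
  n <- nrow(env$features)
  if (n < env$min_features) {
    stop("environment has fewer than min_features candidate features")
  }
  if (is.null(max_steps)) max_steps <- n + 1L
  if (is.null(seed_feature)) seed_feature <- sample.int(n, 1)
  state <- env_graph(env, seed_feature)
  transitions <- list()
  for (s in seq_len(max_steps)) {
    prop <- env_propose(env, state)
    if (prop$dead_end) {
      tr <- structure(list(state = state, action_graph = state, reward = 0,
                           next_proposals = prop, done = TRUE,
                           dead_end = TRUE),
                      class = "transition")
      transitions[[length(transitions) + 1]] <- tr
      break
    }
    n_cand <- length(prop$candidates)
    legal <- if (prop$terminal_allowed) c(seq_len(n_cand), 0L) else seq_len(n_cand)
    act <- if (stats::runif(1) < epsilon) {
      legal[sample.int(length(legal), 1)]
    } else {
      av <- action_values(env, network, prop)
      av$actions[which.max(av$values)]
    }
    tr <- step_env(env, state, act, proposals = prop)
    transitions[[length(transitions) + 1]] <- tr
    state <- tr$action_graph
    if (tr$done || tr$dead_end) break
  }
  transitions
}

#' Q-training configuration
#'
#' @param gamma Reward discount factor in \[0,1\] (default 0.99).
#' @param min_features Minimum pharmacophore size (>= 3; default 3).
#' @param episodes Training episodes per ensemble member (default 300).
#' @param ensemble_size Number of independently seeded members (default 5).
#' @param schedule An [epsilon_schedule()].
#' @param replay_capacity,batch_size Replay-buffer settings.
#' @param learning_rate Adam step size.
#' @param target_sync_every Gradient steps between target-network syncs.
#' @param updates_per_step Gradient steps per environment step.
#' @param hidden Q-network hidden widths.
#' @param seed Base seed; member m uses `seed + m`.
#' @export
q_train_config <- function(gamma = 0.99, min_features = 3L, episodes = 300L,
                           ensemble_size = 5L,
                           schedule = epsilon_schedule(),
                           replay_capacity = 5000L, batch_size = 32L,
                           learning_rate = 3e-3, target_sync_every = 100L,
                           updates_per_step = 2L, hidden = c(64L, 32L),
                           seed = 1L) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (min_features < 3) stop("min_features must be >= 3")
  if (ensemble_size < 1) stop("ensemble_size must be >= 1")
  structure(list(gamma = gamma, min_features = as.integer(min_features),
                 episodes = as.integer(episodes),
                 ensemble_size = as.integer(ensemble_size),
                 schedule = schedule,
                 replay_capacity = as.integer(replay_capacity),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 target_sync_every = as.integer(target_sync_every),
                 updates_per_step = as.integer(updates_per_step),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "q_train_config")
}

# store a transition in replay form: descriptors only
replay_item <- function(env, tr, embedding_size) {
  next_descs <- NULL
  if (!tr$done && !tr$dead_end) {
    np <- tr$next_proposals
    ds <- lapply(np$candidates, env_descriptor, env = env,
                 embedding_size = embedding_size)
    if (np$terminal_allowed) {
      ds <- c(ds, list(env_descriptor(env, tr$action_graph, embedding_size)))
    }
    next_descs <- do.call(rbind, ds)
  }
  list(desc = env_descriptor(env, tr$action_graph, embedding_size),
       reward = tr$reward, terminal = tr$done || tr$dead_end,
       next_descs = next_descs,
       size = nrow(tr$action_graph$features))
}

train_member <- function(envs, config, member_seed) {
  set.seed(member_seed)
  emb <- length(envs[[1]]$features$embedding[[1]])
  network <- q_network(embedding_size = emb, hidden = config$hidden,
                       seed = member_seed)
  target <- network
  opt <- adam_new(network$net)
  replay <- vector("list", config$replay_capacity)
  rpos <- 0L; rcount <- 0L; updates <- 0L
  trace <- vector("list", config$episodes)
  for (ep in seq_len(config$episodes)) {
    env <- envs[[(ep - 1L) %% length(envs) + 1L]]
    eps <- epsilon_at(config$schedule, ep - 1)
    trs <- run_episode(env, network, eps)
    for (tr in trs) {
      rpos <- (rpos %% config$replay_capacity) + 1L
      replay[[rpos]] <- replay_item(env, tr, emb)
      rcount <- min(rcount + 1L, config$replay_capacity)
      if (rcount < config$batch_size) next
      for (u in seq_len(config$updates_per_step)) {
        batch <- replay[sample.int(rcount, config$batch_size)]
        X <- do.call(rbind, lapply(batch, `[[`, "desc"))
        y <- vapply(batch, function(b) {
          if (b$terminal || is.null(b$next_descs)) return(b$reward)
          b$reward + config$gamma * max(q_values_mat(target, b$next_descs))
        }, numeric(1))
        g <- nn_grad(network$net, X, matrix(y, ncol = 1), loss = "mse")
        if (!is.finite(g$loss)) stop("Q-training diverged: non-finite loss")
        stp <- adam_step(network$net, opt, g, lr = config$learning_rate)
        network$net <- stp$net; opt <- stp$opt
        updates <- updates + 1L
        if (updates %% config$target_sync_every == 0L) target <- network
      }
    }
    last <- trs[[length(trs)]]
    trace[[ep]] <- tibble::tibble(
      episode = ep, epsilon = eps,
      episode_return = sum(vapply(trs, `[[`, numeric(1), "reward")),
      final_reward = last$reward,
      final_size = nrow(last$action_graph$features),
      terminated = last$done)
  }
  list(network = network, trace = dplyr::bind_rows(trace))
}

#' Train an ensemble of Q-networks
#'
#' Deep Q-learning with experience replay and a periodically synchronized
#' target network. Episodes are simulated epsilon-greedily with the decaying
#' schedule; the squared temporal-difference error between `Q(G_{t+1})` and
#' `y_t` is minimized, where `y_t = r_t` for terminal and dead-end
#' transitions and `y_t = r_t + gamma * max Q_target` over the next proposal
#' set otherwise. Each ensemble member trains with its own seed.
#'
#' @param envs A `pharm_env` or list of them (cycled per episode).
#' @param config A [q_train_config()].
#' @return A `q_ensemble`: list of members (`network`, `trace`) plus config.
#' @export
train_q <- function(envs, config = q_train_config()) {
  if (inherits(envs, "pharm_env")) envs <- list(envs)
  if (length(envs) == 0) stop("need at least one training environment")
  for (e in envs) e$min_features <- config$min_features
  members <- lapply(seq_len(config$ensemble_size), function(m) {
    train_member(envs, config, config$seed + m)
  })
  structure(list(members = members, config = config), class = "q_ensemble")
}

#' @export
print.q_ensemble <- function(x, ...) {
  fr <- vapply(x$members, function(m) mean(utils::tail(m$trace$final_reward, 20)),
               numeric(1))
  cat("<q_ensemble> ", length(x$members), " members, ",
      x$config$episodes, " episodes each; mean final reward (last 20 ep): ",
      paste(sprintf("%.2f", fr), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.q_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$members), function(m) {
    dplyr::mutate(x$members[[m]]$trace, member = m, .before = 1)
  }))
}

#' Greedy rollout from a seed feature
#'
#' @param env A `pharm_env`.
#' @param network A [q_network()].
#' @param seed_feature Index of the single-feature seed graph.
#' @param max_steps Episode cap.
#' @return Final `pharm_graph` (terminal or dead-end state).
#' @export
greedy_rollout <- function(env, network, seed_feature, max_steps = NULL) {
  trs <- run_episode(env, network, epsilon = 0, seed_feature = seed_feature,
                     max_steps = max_steps)
  trs[[length(trs)]]$action_graph
}

#' Assemble ranked pharmacophores from a trained ensemble
#'
#' For each ensemble member and each of the top-`top_k` seed features
#' (ranked by predictor confidence), runs a greedy rollout and collects the
#' terminal graphs; duplicates are merged and the result ranked by the
#' screening F1 when a library (or reward oracle) is available, by terminal
#' Q-value otherwise. Only graphs reaching `min_features` are returned, so
#' every pharmacophore has at least `min_features` features.
#'
#' @param ensemble A `q_ensemble` from [train_q()].
#' @param features Candidate features (with embeddings and confidences).
#' @param protein A [protein_structure()].
#' @param library Optional molecule library for oracle ranking.
#' @param options List: `min_features` (default from ensemble config),
#'   `top_k` (default 2), `thresholds`, `reward_fn`, matcher options.
#' @return A tibble of ranked pharmacophores with a `pharm` list-column.
#' @export
build_pharmacophore <- function(ensemble, features, protein, library = NULL,
                                options = list()) {
  min_features <- options$min_features %||% ensemble$config$min_features
  top_k <- options$top_k %||% 2L
  thresholds <- options$thresholds %||% graph_thresholds()
  has_oracle <- !is.null(library) || !is.null(options$reward_fn)
  env <- make_env(features, protein, library = library,
                  reward_fn = options$reward_fn %||%
                    (if (is.null(library)) function(graph) 0 else NULL),
                  thresholds = thresholds, min_features = min_features,
                  options = options)
  conf <- features$confidence
  conf[is.na(conf)] <- -Inf
  seeds <- utils::head(order(conf, decreasing = TRUE), top_k)
  rows <- list()
  for (m in seq_along(ensemble$members)) {
    network <- ensemble$members[[m]]$network
    for (sf in seeds) {
      g <- greedy_rollout(env, network, sf)
      if (nrow(g$features) < min_features) next
      rows[[length(rows) + 1]] <- list(
        key = subset_key(g$subset), member = m, seed_feature = sf,
        q = q_value(network, g),
        score = if (has_oracle) env_reward(env, g) else NA_real_,
        graph = g)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(rank = integer(), subset = character(),
                          size = integer(), score = numeric(),
                          q = numeric(), pharm = list()))
  }
  tb <- tibble::tibble(
    key = vapply(rows, `[[`, character(1), "key"),
    member = vapply(rows, function(r) as.integer(r$member), integer(1)),
    seed_feature = vapply(rows, function(r) as.integer(r$seed_feature), integer(1)),
    q = vapply(rows, `[[`, numeric(1), "q"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    graph = lapply(rows, `[[`, "graph"))
  tb$rank_score <- if (has_oracle) tb$score else tb$q
  tb <- tb[order(tb$key, -tb$rank_score), , drop = FALSE]
  tb <- tb[!duplicated(tb$key), , drop = FALSE]
  tb <- tb[order(-tb$rank_score), , drop = FALSE]
  tibble::tibble(
    rank = seq_len(nrow(tb)),
    subset = tb$key,
    size = vapply(tb$graph, function(g) nrow(g$features), integer(1)),
    score = tb$score, q = tb$q,
    pharm = lapply(tb$graph, graph_pharmacophore))
}
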