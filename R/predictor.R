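#' Axis-aligned box
#'
#' @param min,max Numeric length-3 lower/upper corners (Angstrom).
#' @return A `box3` list.
#' @export
box3 <- function(min, max) {
  stopifnot(length(min) == 3, length(max) == 3)
  if (any(max <= min)) stop("box must have positive volume")
  structure(list(min = as.numeric(min), max = as.numeric(max)), class = "box3")
}

#' Bounding box of a point set with padding
#'
#' Used to derive an evaluation box from a reference ligand: the ligand's
#' bounding box plus `pad` Angstrom on every side.
#'
#' @param points Numeric matrix (n x 3) or a feature tibble with x/y/z.
#' @param pad Padding in Angstrom (default 4).
#' @return A [box3()].
#' @export
box_around <- function(points, pad = 4.0) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(points, ncol = 3)
  box3(apply(points, 2, min) - pad, apply(points, 2, max) + pad)
}

#' Translate a box rigidly
#'
#' @param box A [box3()].
#' @param shift Numeric length-3 translation.
#' @export
translate_box <- function(box, shift) box3(box$min + shift, box$max + shift)

grid_axes <- function(box, spacing) {
  lapply(1:3, function(k) seq(box$min[k], box$max[k], by = spacing))
}

grid_points <- function(box, spacing) {
  ax <- grid_axes(box, spacing)
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

# --- reference trainable model ------------------------------------------------

pool_grid <- function(vals, pool) {
  d <- dim(vals)
  if (d[1] %% pool != 0) {
    # grid edge not divisible: drop trailing points (20 -> 5 blocks of 4 ok)
    keep <- d[1] - d[1] %% pool
    vals <- vals[seq_len(keep), seq_len(keep), seq_len(keep), , drop = FALSE]
    d <- dim(vals)
  }
  m <- d[1] %/% pool
  arr <- array(vals, c(pool, m, pool, m, pool, m, d[4]))
  apply(arr, c(2, 4, 6, 7), mean)
}

predictor_input <- function(protein, point, config) {
  g <- voxelize(protein, point, config)
  as.numeric(pool_grid(g$values, config$pool))
}

#' Create the reference trainable site predictor
#'
#' A compact volumetric network: the typed voxel grid is average-pooled
#' (factor `config$pool`) and passed through three dense layers; the final
#' hidden layer of width `config$embedding_size` (32 by default) doubles as
#' the local-environment embedding attached to extracted features, and six
#' independent logistic outputs give the multilabel class confidences.
#'
#' @param config A [predictor_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `site_predictor` model (untrained).
#' @export
site_predictor <- function(config = predictor_config(), seed = 1L) {
  m <- (config$n_points %/% config$pool)
  input <- m^3 * length(config$channels)
  net <- nn_new(c(input, config$hidden, config$embedding_size, 6L), seed = seed)
  structure(list(net = net, config = config, trace = NULL),
            class = "site_predictor")
}

#' @export
print.site_predictor <- function(x, ...) {
  cat("<site_predictor> layers ", paste(x$net$sizes, collapse = "-"),
      if (is.null(x$trace)) " (untrained)\n" else
        sprintf(" (trained, final loss %.4f)\n", utils::tail(x$trace, 1)),
      sep = "")
  invisible(x)
}

#' Evaluate a predictor at a set of points
#'
#' Generic over predictor models (the trainable [site_predictor()], the
#' closed-form oracle predictor of [make_pocket()], or a constant model).
#'
#' @param model Predictor model.
#' @param protein A [protein_structure()].
#' @param points Numeric matrix (n x 3).
#' @return List with `confidences` (n x 6 matrix, columns in class order) and
#'   `embedding` (n x embedding_size matrix).
#' @export
predict_confidences <- function(model, protein, points) {
  UseMethod("predict_confidences")
}

#' @export
predict_confidences.site_predictor <- function(model, protein, points) {
  points <- matrix(points, ncol = 3)
  X <- t(vapply(seq_len(nrow(points)),
                function(i) predictor_input(protein, points[i, ], model$config),
                numeric(model$net$sizes[1])))
  a <- nn_forward(model$net, X)
  conf <- sigmoid(a[[length(a)]])
  colnames(conf) <- pharm_classes()
  list(confidences = conf, embedding = a[[length(a) - 1]])
}

#' A constant-logit predictor (diagnostic)
#'
#' Returns identical confidences everywhere; with `logit = 0` every class
#' confidence is exactly 0.5. Useful as a null model in tests.
#'
#' @param logit Constant logit per class (scalar or length-6).
#' @param embedding_size Embedding width.
#' @export
constant_predictor <- function(logit = 0, embedding_size = 32L) {
  structure(list(logit = rep_len(logit, 6), embedding_size = embedding_size),
            class = "constant_predictor")
}

#' @export
predict_confidences.constant_predictor <- function(model, protein, points) {
  n <- nrow(matrix(points, ncol = 3))
  conf <- matrix(rep(sigmoid(model$logit), each = n), nrow = n)
  colnames(conf) <- pharm_classes()
  list(confidences = conf,
       embedding = matrix(0, n, model$embedding_size))
}

#' Predict feature-class confidences and embedding at one point
#'
#' @param model Predictor model.
#' @param protein A [protein_structure()].
#' @param point Numeric length-3 position.
#' @param config Unused for oracle models; for a [site_predictor()] the
#'   model's own config is used (a mismatching config is an error).
#' @return List with `confidences` (named length-6 vector) and `embedding`.
#' @export
predict_point <- function(model, protein, point, config = NULL) {
  if (inherits(model, "site_predictor") && !is.null(config)) {
    if (!identical(config$n_points, model$config$n_points) ||
        length(config$channels) != length(model$config$channels)) {
      stop("predictor config does not match the model's input shape")
    }
  }
  p <- predict_confidences(model, protein, matrix(point, ncol = 3))
  list(confidences = stats::setNames(as.numeric(p$confidences[1, ]),
                                     pharm_classes()),
       embedding = as.numeric(p$embedding[1, ]))
}

# --- training ----------------------------------------------------------------

#' Construct a training sample for the site predictor
#'
#' @param protein A [protein_structure()] providing the local environment.
#' @param point Numeric length-3 sample position.
#' @param labels Length-6 0/1 vector in class order (all zero for negatives).
#' @param is_adversarial Whether this is a mined adversarial negative (all
#'   labels must then be zero).
#' @export
training_sample <- function(protein, point, labels,
                            is_adversarial = FALSE) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == 6, all(labels %in% c(0, 1)))
  if (is_adversarial && any(labels != 0)) {
    stop("adversarial samples must carry all-zero labels")
  }
  structure(list(protein = protein, point = as.numeric(point),
                 labels = labels, is_adversarial = isTRUE(is_adversarial)),
            class = "training_sample")
}

#' Train the site predictor
#'
#' Minimizes per-class binary cross-entropy over a set of labelled points
#' (multilabel: classes are independent logistic outputs). Reproducible for a
#' fixed seed; returns the model with its training-loss trace attached.
#'
#' @param samples List of [training_sample()] objects (at least one positive
#'   and one negative).
#' @param config A [predictor_config()].
#' @param seed Integer seed (initialization and batch order).
#' @param epochs,lr,batch_size Optimization settings.
#' @return A trained `site_predictor`.
#' @export
train_predictor <- function(samples, config = predictor_config(), seed = 1L,
                            epochs = 150L, lr = 3e-3, batch_size = 32L) {
  if (length(samples) < 2) stop("need at least two training samples")
  Y <- do.call(rbind, lapply(samples, function(s) s$labels))
  has_pos <- any(rowSums(Y) > 0); has_neg <- any(rowSums(Y) == 0)
  if (!has_pos || !has_neg) {
    warning("degenerate training set: only one label polarity present")
  }
  model <- site_predictor(config, seed = seed)
  X <- t(vapply(samples,
                function(s) predictor_input(s$protein, s$point, config),
                numeric(model$net$sizes[1])))
  fit <- nn_train(model$net, X, Y, loss = "bce", epochs = epochs, lr = lr,
                  batch_size = batch_size, seed = seed + 1L)
  model$net <- fit$net
  model$trace <- fit$trace
  model
}

#' Mine adversarial negative samples
#'
#' Evaluates the predictor on a 0.5-Angstrom grid over `box` and flags
#' physically implausible firings as all-zero-label negatives: points whose
#' fired class (confidence > `threshold`) either clashes with the protein
#' (nearest heavy atom closer than `d_clash`) or lacks its complementary
#' functional group within the per-class distance `d_comp` (a hydrogen
#' acceptor more than 4 Angstrom from every protein donor group, for
#' instance). Re-running on a model that no longer fires at the flagged
#' points adds nothing.
#'
#' @param model Predictor model.
#' @param protein A [protein_structure()] with annotated groups.
#' @param box A [box3()] to mine over.
#' @param config A [predictor_config()].
#' @param threshold Firing threshold (default 0.5).
#' @param d_clash Clash distance to the nearest heavy atom (default 2.0).
#' @param d_comp Per-class complementary distances, see [default_comp_dist()].
#' @param spacing Grid spacing (default 0.5).
#' @return List of adversarial [training_sample()] objects.
#' @export
generate_adversarial_negatives <- function(model, protein, box,
                                           config = predictor_config(),
                                           threshold = 0.5, d_clash = 2.0,
                                           d_comp = default_comp_dist(),
                                           spacing = 0.5) {
  pts <- grid_points(box, spacing)
  pred <- predict_confidences(model, protein, pts)
  fired <- pred$confidences > threshold
  any_fired <- rowSums(fired) > 0
  if (!any(any_fired)) return(list())
  hv <- heavy_coords(protein)
  keep <- which(any_fired)
  d_heavy <- if (nrow(hv) > 0) {
    apply(cross_dist(pts[keep, , drop = FALSE], hv), 1, min)
  } else rep(Inf, length(keep))
  flagged <- logical(length(keep))
  flagged[d_heavy < d_clash] <- TRUE
  for (cls in pharm_classes()) {
    ci <- match(cls, pharm_classes())
    rows <- which(fired[keep, ci])
    if (!length(rows)) next
    gc <- group_coords(protein, complement_of()[[cls]])
    if (nrow(gc) == 0) {
      flagged[rows] <- TRUE
      next
    }
    dmin <- apply(cross_dist(pts[keep[rows], , drop = FALSE], gc), 1, min)
    flagged[rows[dmin > d_comp[[cls]]]] <- TRUE
  }
  lapply(keep[flagged], function(i) {
    training_sample(protein, pts[i, ], rep(0, 6), is_adversarial = TRUE)
  })
}
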