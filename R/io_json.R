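#' Read a Pharmit-compatible pharmacophore JSON file
#'
#' Expects a JSON object with a `points` array of
#' `{name, x, y, z, radius, enabled, svector?}` entries. Point names map
#' one-to-one onto the six feature classes ("Aromatic", "HydrogenDonor",
#' "HydrogenAcceptor", "Hydrophobic", "NegativeIon", "PositiveIon").
#' Points with `"enabled": false` are skipped. Direction vectors (`svector`)
#' are stored on the feature but ignored by the matcher.
#'
#' @param path Path to the JSON file.
#' @param name Pharmacophore name (defaults to the file name).
#' @return A [pharmacophore()].
#' @export
read_pharmacophore <- function(path, name = NULL) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse pharmacophore JSON ",
                                           path, ": ", conditionMessage(e),
                                           call. = FALSE))
  pts <- obj$points
  if (is.null(pts)) stop("pharmacophore JSON has no \"points\" array: ", path)
  rows <- list(); dirs <- list()
  for (p in pts) {
    if (!is.null(p$enabled) && !isTRUE(p$enabled)) next
    if (is.null(p$name) || !(p$name %in% pharm_classes())) {
      stop("unknown pharmacophore point name \"", p$name, "\"; accepted: ",
           paste(pharm_classes(), collapse = ", "))
    }
    rows[[length(rows) + 1]] <- list(
      class = p$name, x = as.numeric(p$x), y = as.numeric(p$y),
      z = as.numeric(p$z),
      radius = if (is.null(p$radius)) 1.0 else as.numeric(p$radius))
    dirs[[length(rows)]] <- if (!is.null(p$svector)) {
      as.numeric(c(p$svector$x, p$svector$y, p$svector$z))
    } else c(NA_real_, NA_real_, NA_real_)
  }
  if (is.null(name)) name <- sub("\\.json$", "", basename(path))
  if (length(rows) == 0) {
    return(pharmacophore(pharm_features(character(), numeric(), numeric(),
                                        numeric()), name))
  }
  df <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  dm <- do.call(rbind, dirs)
  feats <- pharm_features(df$class, df$x, df$y, df$z, radius = df$radius)
  feats$dir_x <- dm[, 1]; feats$dir_y <- dm[, 2]; feats$dir_z <- dm[, 3]
  pharmacophore(feats, name)
}

#' Write a pharmacophore as Pharmit-compatible JSON
#'
#' Writing then reading is the identity on features (positions to 1e-6
#' Angstrom, class, radius, direction). All points are written enabled.
#'
#' @param pharm A [pharmacophore()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(pharm, path) {
  stopifnot(inherits(pharm, "pharmacophore"))
  f <- pharm$features
  pts <- lapply(seq_len(nrow(f)), function(i) {
    p <- list(name = f$class[i], x = f$x[i], y = f$y[i], z = f$z[i],
              radius = f$radius[i], enabled = TRUE)
    if (!is.na(f$dir_x[i])) {
      p$svector <- list(x = f$dir_x[i], y = f$dir_y[i], z = f$dir_z[i])
    }
    p
  })
  jsonlite::write_json(list(points = pts), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

feature_list_to_json <- function(f) {
  lapply(seq_len(nrow(f)), function(i) {
    list(class = f$class[i], x = f$x[i], y = f$y[i], z = f$z[i],
         radius = f$radius[i])
  })
}

json_to_features <- function(lst) {
  df <- dplyr::bind_rows(lapply(lst, tibble::as_tibble))
  pharm_features(df$class, df$x, df$y, df$z, radius = df$radius)
}

#' Read a molecule feature library from JSON Lines
#'
#' One molecule record per line: an object with fields `id`, `is_active`,
#' `features` (array of `{class, x, y, z, radius}`) and optional `atoms`
#' (array of `[x, y, z]` triples used for receptor-exclusion checks).
#'
#' @param path Path to a `.jsonl` file.
#' @return A list of [molecule_record()] objects.
#' @export
read_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) stop("library JSONL parse error at line ",
                                             i, ": ", conditionMessage(e),
                                             call. = FALSE))
    atoms <- if (!is.null(obj$atoms)) {
      do.call(rbind, lapply(obj$atoms, as.numeric))
    } else NULL
    molecule_record(obj$id, json_to_features(obj$features), atoms = atoms,
                    is_active = isTRUE(obj$is_active))
  })
}

#' Write a molecule feature library as JSON Lines
#'
#' @param library List of [molecule_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  lines <- vapply(library, function(m) {
    obj <- list(id = m$id, is_active = m$is_active,
                features = feature_list_to_json(m$features))
    if (!is.null(m$atoms)) {
      obj$atoms <- lapply(seq_len(nrow(m$atoms)), function(i) m$atoms[i, ])
    }
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write features as a Pharmit JSON feature file
#'
#' Convenience wrapper: serializes a feature table (e.g. the output of
#' [extract_features()]) as a pharmacophore JSON with all points enabled.
#' Confidences and embeddings are written under an `apopharm` extension block
#' so that [read_features()] can restore them.
#'
#' @param features A [pharm_features()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  pts <- lapply(seq_len(nrow(features)), function(i) {
    p <- list(name = features$class[i], x = features$x[i], y = features$y[i],
              z = features$z[i], radius = features$radius[i], enabled = TRUE)
    if (!is.na(features$confidence[i])) p$confidence <- features$confidence[i]
    if (!is.null(features$embedding[[i]])) p$embedding <- features$embedding[[i]]
    p
  })
  jsonlite::write_json(list(points = pts), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature file written by [write_features()]
#'
#' @param path Path to the JSON file.
#' @return A [pharm_features()] tibble (with confidences/embeddings if stored).
#' @export
read_features <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pts <- obj$points
  if (is.null(pts)) stop("feature JSON has no \"points\" array: ", path)
  cls <- vapply(pts, function(p) as.character(p$name), character(1))
  assert_class(cls)
  feats <- pharm_features(
    cls,
    vapply(pts, function(p) as.numeric(p$x), numeric(1)),
    vapply(pts, function(p) as.numeric(p$y), numeric(1)),
    vapply(pts, function(p) as.numeric(p$z), numeric(1)),
    radius = vapply(pts, function(p) if (is.null(p$radius)) 1 else as.numeric(p$radius), numeric(1)),
    confidence = vapply(pts, function(p) if (is.null(p$confidence)) NA_real_ else as.numeric(p$confidence), numeric(1))
  )
  feats$embedding <- lapply(pts, function(p) {
    if (is.null(p$embedding)) NULL else as.numeric(unlist(p$embedding))
  })
  feats
}
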