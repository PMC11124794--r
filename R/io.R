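# Readers/writers for landmark files. Two formats:
#  * CSV: one row per landmark per frame, header
#      sequence_id,frame,landmark,x,y,z,visibility   (visibility may be empty)
#    `landmark` is a registry name or a MediaPipe index (0-32).
#  * JSONL: one frame object per line,
#      {"sequence_id": ..., "frame": ..., "landmarks": {name: [x,y,z(,vis)]}}
# Facial landmarks (MediaPipe indices 0-10), if present, are silently dropped
# so raw full-body dumps load directly.

.FACIAL_NAMES <- c(
  "nose", "left_eye_inner", "left_eye", "left_eye_outer",
  "right_eye_inner", "right_eye", "right_eye_outer",
  "left_ear", "right_ear", "mouth_left", "mouth_right"
)

# Resolve a landmark column that may mix names and numeric indices.
# Returns canonical names, NA for facial landmarks (to be dropped).
.canon_landmark <- function(lm, file) {
  lm <- as.character(lm)
  out <- rep(NA_character_, length(lm))
  idx <- suppressWarnings(as.integer(lm))
  is_num <- !is.na(idx) & grepl("^\\s*\\d+\\s*$", lm)
  facial_num <- is_num & idx >= 0 & idx <= 10
  body_num <- is_num & idx >= 11 & idx <= 32
  out[body_num] <- .index_landmark_map()[as.character(idx[body_num])]
  named <- !is_num
  known_body <- named & lm %in% .LANDMARK_NAMES
  known_facial <- named & lm %in% .FACIAL_NAMES
  out[known_body] <- lm[known_body]
  bad <- which(!(facial_num | body_num | known_body | known_facial))
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "%s: unknown landmark %s (data line %d).",
      file, sQuote(lm[bad[1]]), bad[1]
    ))
  }
  out # NA marks facial rows
}

#' Read a pose-landmark sequence from disk
#'
#' Reads one landmark sequence from a CSV or JSONL file (see Details for the
#' layouts), drops facial landmarks (MediaPipe indices 0--10) if present, and
#' validates that every frame carries exactly the 22 body landmarks.
#'
#' @details
#' CSV files have the header `sequence_id,frame,landmark,x,y,z,visibility`
#' (the `visibility` column is optional and may be empty), one row per
#' landmark per frame; `landmark` is a registry name or a MediaPipe numeric
#' index. JSONL files hold one frame object per line:
#' `{"sequence_id": id, "frame": i, "landmarks": {"left_knee": [x, y, z]}}`,
#' with an optional fourth element per landmark for visibility.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension.
#' @param fps Frame rate to attach (not stored in the files). Default 30.
#' @param label Optional exercise label to attach.
#' @return A [pose_sequence()].
#' @export
read_sequence <- function(path, format = NULL, fps = 30, label = NULL) {
  if (!file.exists(path)) {
    abort_validation(paste0("File not found: ", path))
  }
  format <- format %||% .guess_format(path)
  format <- match.arg(format, c("csv", "jsonl"))
  df <- switch(format,
    csv = .read_sequence_csv(path),
    jsonl = .read_sequence_jsonl(path)
  )
  ids <- unique(df$sequence_id)
  if (length(ids) != 1) {
    abort_validation(paste0(
      path, ": expected a single sequence per file, found ",
      length(ids), " sequence ids."
    ))
  }
  pose_sequence(df, fps = fps, label = label)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
}

.read_sequence_csv <- function(path) {
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      sequence_id = readr::col_character(),
      frame = readr::col_double(),
      landmark = readr::col_character(),
      # coordinates come in as text and go through strtod (correctly
      # rounded), keeping the write/read cycle bit-exact
      x = readr::col_character(),
      y = readr::col_character(),
      z = readr::col_character(),
      .default = readr::col_character()
    ),
    progress = FALSE
  ))
  for (col in intersect(c("x", "y", "z", "visibility"), names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad) > 0) {
      abort_parse(sprintf(
        "%s: malformed row at line %d (non-numeric %s).",
        path, bad[1] + 1L, col
      ))
    }
    df[[col]] <- val
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort_parse(sprintf(
      "%s: malformed row at line %d (%s).",
      path, probs$row[[1]] + 1L, probs$expected[[1]]
    ))
  }
  needed <- c("sequence_id", "frame", "landmark", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort_parse(paste0(
      path, ": missing column(s): ", paste(missing_cols, collapse = ", "), "."
    ))
  }
  bad <- which(is.na(df$frame) | is.na(df$x) | is.na(df$y) | is.na(df$z))
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "%s: malformed row at line %d (missing frame or coordinate).",
      path, bad[1] + 1L
    ))
  }
  df$landmark <- .canon_landmark(df$landmark, path)
  df[!is.na(df$landmark), ]
}

.read_sequence_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_parse(paste0(path, ": empty file."))
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        abort_parse(sprintf("%s: malformed JSON at line %d.", path, i))
      }
    )
    if (is.null(obj$frame) || is.null(obj$landmarks)) {
      abort_parse(sprintf(
        "%s: line %d lacks 'frame' or 'landmarks'.", path, i
      ))
    }
    lms <- obj$landmarks
    nm <- .canon_landmark(names(lms), path)
    keep <- !is.na(nm)
    lms <- lms[keep]
    nm <- nm[keep]
    coords <- do.call(rbind, lapply(lms, function(v) {
      v <- as.numeric(v)
      if (!(length(v) %in% c(3L, 4L))) {
        abort_parse(sprintf(
          "%s: line %d: landmark must be [x,y,z] or [x,y,z,visibility].", path, i
        ))
      }
      c(v, rep(NA_real_, 4L - length(v)))
    }))
    rows[[i]] <- tibble::tibble(
      sequence_id = as.character(obj$sequence_id %||% "seq"),
      frame = as.integer(obj$frame),
      landmark = nm,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      visibility = coords[, 4]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$visibility))) out$visibility <- NULL
  out
}

#' Write a pose-landmark sequence to disk
#'
#' Serializes a [pose_sequence()] as CSV or JSONL with full double precision,
#' so `read_sequence(write_sequence(x))` reproduces `x` exactly.
#'
#' @param seq A `pose_sequence`.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = NULL) {
  if (!inherits(seq, "pose_sequence")) {
    seq <- pose_sequence(seq)
  }
  format <- format %||% .guess_format(path)
  format <- match.arg(format, c("csv", "jsonl"))
  if (format == "csv") {
    out <- tibble::as_tibble(seq)
    # full double precision so the round trip is bit-exact
    for (col in intersect(c("x", "y", "z", "visibility"), names(out))) {
      out[[col]] <- sprintf("%.17g", out[[col]])
      out[[col]][out[[col]] == "NA"] <- ""
    }
    readr::write_csv(out, path, progress = FALSE, na = "")
  } else {
    has_vis <- "visibility" %in% names(seq) && !all(is.na(seq$visibility))
    frames <- split(seq, seq$frame)
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (fr in frames) {
      lms <- lapply(seq_len(nrow(fr)), function(i) {
        v <- c(fr$x[i], fr$y[i], fr$z[i])
        if (has_vis && !is.na(fr$visibility[i])) v <- c(v, fr$visibility[i])
        v
      })
      names(lms) <- fr$landmark
      writeLines(jsonlite::toJSON(
        list(
          sequence_id = fr$sequence_id[[1]],
          frame = fr$frame[[1]],
          landmarks = lms
        ),
        auto_unbox = TRUE, digits = I(17)
      ), con)
    }
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with header `sequence_id,label,path` (extra columns,
#' e.g. per-sequence seeds, are preserved). Labels are validated against the
#' class registry and sequence ids must be unique. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with columns `sequence_id`, `label`, `path` (absolute)
#'   plus any extra columns present.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("Manifest not found: ", path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    sequence_id = readr::col_character(),
    label = readr::col_character(),
    path = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  needed <- c("sequence_id", "label", "path")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort_parse(paste0(
      path, ": manifest is missing column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  if (anyDuplicated(df$sequence_id) > 0) {
    dupes <- unique(df$sequence_id[duplicated(df$sequence_id)])
    abort_validation(paste0(
      "Duplicate sequence_id in manifest: ",
      paste(utils::head(dupes, 5), collapse = ", "), "."
    ))
  }
  df$label <- normalize_class(df$label)
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

#' Load all sequences listed in a manifest
#'
#' @param manifest Path to a manifest CSV, or a tibble as returned by
#'   [read_manifest()].
#' @param fps Frame rate to attach to every sequence.
#' @return A named list of labelled [pose_sequence()] objects.
#' @export
load_dataset <- function(manifest, fps = 30) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  seqs <- purrr::map2(
    manifest$path, manifest$label,
    function(p, lab) read_sequence(p, fps = fps, label = lab)
  )
  stats::setNames(seqs, manifest$sequence_id)
}
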