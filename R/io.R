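# Readers and writers for the on-disk run formats:
#   detections.csv   one row per per-frame plant detection
#   depth/*.pgm      16-bit binary PGM, millimeters, 0 = invalid
#   motion.csv       per-frame along-track displacement
#   intrinsics.cfg   key = value camera/acquisition config
#   report.json      sowing-quality report

#' Read a per-frame detection table
#'
#' Expects the CSV schema `frame_index,timestamp_s,x_min,y_min,x_max,
#' y_max,kp_x,kp_y,confidence`. Rows failing basic validity (non-numeric
#' fields, inverted boxes) abort with the offending line number.
#'
#' @param path CSV file path.
#' @return Data frame sorted by `frame_index`, with the columns above.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  det <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "timestamp_s", .det_cols[-1])
  miss <- setdiff(need, names(det))
  if (length(miss))
    stop("detections file ", path, " lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in need) {
    v <- det[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", col, "' at data line ",
             bad[1L], " of ", path, call. = FALSE)
      det[[col]] <- vn
    }
  }
  bad <- which(det$x_min >= det$x_max | det$y_min >= det$y_max)
  if (length(bad))
    stop("malformed bbox (x_min >= x_max or y_min >= y_max) at data line ",
         bad[1L], " of ", path, call. = FALSE)
  det$frame_index <- as.integer(det$frame_index)
  det[order(det$frame_index), , drop = FALSE]
}

#' Write a detection table
#'
#' @param det Detection data frame (see [read_detections()] for schema).
#' @param path Output CSV path.
#' @export
write_detections <- function(det, path) {
  cols <- c("frame_index", "timestamp_s", .det_cols[-1])
  utils::write.csv(.num_fmt(det[, cols, drop = FALSE]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 16-bit depth PGM
#'
#' Binary (P5) PGM with maxval 65535; pixel values are depth in
#' millimeters and 0 marks an invalid pixel. Values are converted to
#' meters and invalid pixels masked.
#'
#' @param path PGM file path.
#' @param frame_index Depth-stream frame index to record on the frame.
#' @return A [depth_frame()].
#' @export
read_depth_pgm <- function(path, frame_index = 0L) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- .pgm_tokens(con, 4L)
  if (tok[1L] != "P5")
    stop(path, ": not a binary (P5) PGM", call. = FALSE)
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  maxval <- as.integer(tok[4L])
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop(path, ": bad PGM dimensions", call. = FALSE)
  if (is.na(maxval) || maxval != 65535L)
    stop(path, ": expected 16-bit PGM (maxval 65535), got maxval ",
         tok[4L], call. = FALSE)
  raw_mm <- readBin(con, "integer", n = w * h, size = 2L, signed = FALSE,
                    endian = "big")
  if (length(raw_mm) != w * h)
    stop(path, ": truncated PGM payload", call. = FALSE)
  vals <- matrix(raw_mm / 1000, nrow = h, ncol = w, byrow = TRUE)
  depth_frame(vals, frame_index = frame_index)
}

# Whitespace/comment-aware header tokenizer for PGM.
.pgm_tokens <- function(con, n) {
  tok <- character(0)
  cur <- ""
  in_comment <- FALSE
  while (length(tok) < n || nzchar(cur)) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("unexpected end of PGM header", call. = FALSE)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(cur)) { tok <- c(tok, cur); cur <- "" }
      if (length(tok) == n) break
    } else cur <- paste0(cur, ch)
  }
  tok
}

#' Write a depth map as a 16-bit PGM
#'
#' @param values Numeric matrix of depths in meters; `NA`/non-finite or
#'   non-positive entries are written as 0 (invalid). Values are rounded
#'   to integer millimeters and clipped to 65535.
#' @param path Output file path.
#' @export
write_depth_pgm <- function(values, path) {
  stopifnot(is.matrix(values))
  mm <- round(values * 1000)
  mm[!is.finite(mm) | mm <= 0] <- 0
  mm <- pmin(mm, 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", ncol(values), nrow(values)), con,
            eos = NULL)
  writeBin(as.integer(t(mm)), con, size = 2L, endian = "big")
  invisible(path)
}

#' Read/write a platform motion table
#'
#' CSV with columns `frame_index,displacement_m`.
#'
#' @param path CSV file path.
#' @return [read_motion()]: a [platform_motion()] in per-frame mode.
#' @export
read_motion <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  platform_motion(table = tab)
}

#' @param motion A [platform_motion()] or a data frame with
#'   `frame_index,displacement_m`.
#' @param frames Frame indices to tabulate (constant-speed mode).
#' @rdname read_motion
#' @export
write_motion <- function(motion, path, frames = NULL) {
  if (is.data.frame(motion)) tab <- motion
  else if (motion$mode == "per_frame_table") tab <- motion$table
  else {
    if (is.null(frames))
      stop("constant-speed motion needs explicit `frames` to tabulate",
           call. = FALSE)
    tab <- data.frame(frame_index = frames,
                      displacement_m = displacement_at(motion, frames))
  }
  utils::write.csv(.num_fmt(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write the camera + acquisition config
#'
#' Plain-text `key = value` config carrying the camera intrinsics (`fx`,
#' `fy`, `cx`, `cy`, `width`, `height`), the stream rates (`rgb_rate`,
#' `depth_rate`) and the mount height (`camera_height_m`).
#'
#' @param path Config file path.
#' @return [read_intrinsics()]: a list with `intrinsics` (a
#'   [camera_intrinsics()]), `rgb_rate`, `depth_rate`, `camera_height_m`.
#' @export
read_intrinsics <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop(path, ": malformed config line: ", lines[bad][1L], call. = FALSE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  need <- c("fx", "fy", "cx", "cy", "width", "height",
            "rgb_rate", "depth_rate", "camera_height_m")
  miss <- setdiff(need, names(vals))
  if (length(miss))
    stop(path, ": missing config keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- suppressWarnings(as.numeric(vals[need]))
  if (anyNA(num))
    stop(path, ": non-numeric config value", call. = FALSE)
  names(num) <- need
  list(intrinsics = camera_intrinsics(num["fx"], num["fy"], num["cx"],
                                      num["cy"], num["width"], num["height"]),
       rgb_rate = unname(num["rgb_rate"]),
       depth_rate = unname(num["depth_rate"]),
       camera_height_m = unname(num["camera_height_m"]))
}

#' @param K A [camera_intrinsics()].
#' @param rgb_rate,depth_rate Stream frame rates, frames/s.
#' @param camera_height_m Camera mount height above ground, meters.
#' @rdname read_intrinsics
#' @export
write_intrinsics <- function(K, rgb_rate, depth_rate, camera_height_m, path) {
  stopifnot(inherits(K, "camera_intrinsics"))
  vals <- c(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
            width = K$width, height = K$height,
            rgb_rate = rgb_rate, depth_rate = depth_rate,
            camera_height_m = camera_height_m)
  writeLines(sprintf("%s = %s", names(vals),
                     formatC(vals, digits = 9, format = "g")), path)
  invisible(path)
}

#' Write a sowing-quality report as JSON
#'
#' @param report A `"sowing_quality"` object from [evaluate_sowing()].
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sowing_quality"))
  obj <- list(qfi_pct = report$qfi, mul_pct = report$mul,
              mi_pct = report$mi, s_bar = report$s_bar,
              sigma = report$sigma, cv_pct = report$cv,
              bins = as.list(report$bins),
              counts = list(n0 = report$counts$n0, n1 = report$counts$n1,
                            n2 = report$counts$n2, N = report$counts$Np),
              n_spacings = report$n_spacings,
              target_spacing_m = report$target,
              sigma_formula = report$sigma_formula,
              valid = report$valid,
              warnings = as.list(report$warnings))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a sowing-quality report written by [write_report()]
#'
#' @param path JSON path.
#' @return The parsed report as a list (not a `"sowing_quality"` object).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Serialize numerics with 9 significant digits for text output.
.num_fmt <- function(df) {
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.double(v)) df[[nm]] <- formatC(v, digits = 9, format = "g")
  }
  df
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
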