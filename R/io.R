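# Readers and writers shared by all modules. Conventions: images are PNG;
# masks are single-channel PNG with values {0, 255}; landmarks are CSV with
# header `name,x,y` in 0-based pixel coordinates (x = column, y = row);
# contours and manifests are JSON.

#' Write / read an RGB image as PNG
#'
#' @param image `H x W x 3` array, values 0-255.
#' @param path file path.
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @return `read_image()` returns an `H x W x 3` array with values 0-255.
#' @export
read_image <- function(path) {
  x <- tryCatch(png::readPNG(path), error = function(e)
    stop("not a readable PNG image: ", path, " (", conditionMessage(e), ")"))
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Write / read a binary mask as single-channel PNG ({0, 255})
#'
#' @param mask `H x W` matrix, nonzero = foreground.
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @return `read_mask()` returns an `H x W` matrix of 0/1.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x >= 0.5) * 1
}

#' Write / read landmarks as CSV (`name,x,y`, 0-based pixel coordinates)
#'
#' @param landmarks named `N x 2` matrix.
#' @param path file path.
#' @param one_based read/write 1-based coordinates (shifted by exactly 1).
#' @export
write_landmarks <- function(landmarks, path, one_based = FALSE) {
  off <- if (one_based) 1 else 0
  nm <- rownames(landmarks)
  if (is.null(nm)) nm <- paste0("p", seq_len(nrow(landmarks)))
  df <- data.frame(name = nm, x = landmarks[, 1] + off, y = landmarks[, 2] + off)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @return `read_landmarks()` returns a named `N x 2` matrix.
#' @export
read_landmarks <- function(path, one_based = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have header name,x,y: ", path)
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(xs) | !is.finite(ys))
  if (length(bad)) stop("malformed landmark CSV at line ", bad[1] + 1L)
  off <- if (one_based) 1 else 0
  m <- cbind(x = xs - off, y = ys - off)
  rownames(m) <- df$name
  m
}

#' Read a custom lip template from CSV
#'
#' The CSV must contain columns `x,y` describing an ordered, closed, simple
#' polyline (the closing edge is implicit).
#'
#' @param path file path.
#' @return a `lip_template`.
#' @export
read_template <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df))) stop("template CSV must have columns x,y")
  new_lip_template(cbind(df$x, df$y))
}

#' Write / read a contour as a JSON point list
#'
#' @param contour `n x 2` matrix (0-based x, y).
#' @param path file path.
#' @export
write_contour <- function(contour, path) {
  jsonlite::write_json(list(coordinates = "0-based, x = column, y = row",
                            points = unname(apply(contour, 1, as.numeric,
                                                  simplify = FALSE))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- j$points
  m <- if (is.matrix(p)) p else do.call(rbind, lapply(p, as.numeric))
  colnames(m) <- c("x", "y")
  m
}

#' Write a cohort to disk
#'
#' Images as `img_####.png`, masks as `mask_####.png`, landmarks as
#' `lm_####.csv`, plus a JSON `manifest.json` with labels, cohorts and
#' grades.
#'
#' @param samples list of `lip_sample` objects.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    id <- sprintf("%04d", i)
    write_image(s$image, file.path(dir, paste0("img_", id, ".png")))
    write_mask(s$mask, file.path(dir, paste0("mask_", id, ".png")))
    write_landmarks(s$landmarks, file.path(dir, paste0("lm_", id, ".csv")))
    list(id = id, label = s$label, cohort = s$cohort, vbls_grade = s$vbls_grade)
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Save / load model parameters as flat CSV (portable text checkpoints)
#'
#' Each parameter array is stored with its name, dimensions and values; a
#' JSON sidecar records the model class and spec.
#'
#' @param model any model object with a `params` list (or `saunet`).
#' @param path base path; `.csv.gz` and `.json` files are written.
#' @export
save_model <- function(model, path) {
  flat <- flatten_model(model)
  con <- gzfile(paste0(path, ".csv.gz"), "w")
  on.exit(close(con), add = TRUE)
  df <- data.frame(name = rep(names(flat$arrays),
                              vapply(flat$arrays, length, 0L)),
                   value = sprintf("%.17g", unlist(flat$arrays, use.names = FALSE)))
  write.csv(df, con, row.names = FALSE)
  jsonlite::write_json(flat$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

flatten_model <- function(model) {
  if (inherits(model, "saunet")) {
    a1 <- model$stage1$params; a2 <- model$stage2$params
    names(a1) <- paste0("stage1.", names(a1))
    names(a2) <- paste0("stage2.", names(a2))
    arrays <- c(a1, a2)
    meta <- list(class = "saunet", trained = isTRUE(model$trained),
                 spec1 = unclass(model$stage1$spec), spec2 = unclass(model$stage2$spec),
                 dims = lapply(arrays, function(p) dim(p) %||% length(p)))
  } else {
    arrays <- model$params
    meta <- list(class = class(model)[1], trained = isTRUE(model$trained),
                 spec = unclass(model$spec),
                 dims = lapply(arrays, function(p) dim(p) %||% length(p)))
  }
  list(arrays = arrays, meta = meta)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(gzfile(paste0(path, ".csv.gz")))
  vals <- split(df$value, factor(df$name, levels = unique(df$name)))
  shape <- function(nm) {
    d <- unlist(meta$dims[[nm]])
    v <- as.numeric(vals[[nm]])
    if (length(d) > 1L) array(v, d) else v
  }
  params <- lapply(stats::setNames(names(vals), names(vals)), shape)
  if (meta$class == "saunet") {
    pick <- function(pre) {
      p <- params[startsWith(names(params), pre)]
      names(p) <- substring(names(p), nchar(pre) + 1L)
      p
    }
    s1 <- structure(list(spec = restore_spec(meta$spec1), params = pick("stage1."),
                         trained = meta$trained), class = "aunet")
    s2 <- structure(list(spec = restore_spec(meta$spec2), params = pick("stage2."),
                         trained = meta$trained), class = "aunet")
    structure(list(stage1 = s1, stage2 = s2, trained = meta$trained),
              class = "saunet")
  } else {
    structure(list(spec = restore_spec(meta$spec), params = params,
                   trained = meta$trained), class = meta$class)
  }
}

restore_spec <- function(sp) {
  sp <- lapply(sp, function(v) if (is.numeric(v)) as.integer(v) else v)
  class(sp) <- "aunet_spec"
  sp
}
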