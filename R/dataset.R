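# TongueDataset: the on-disk/in-memory container pairing images, text
# records and the two multi-label target matrices.

#' @import methods
NULL

#' TongueDataset
#'
#' S4 container for a tongue image/text multi-label dataset: a manifest
#' (one row per sample: image path, split tag), the pathology (n x 10) and
#' location (n x 9) binary target matrices, the text records, and
#' optionally the decoded image arrays held in memory.
#'
#' @slot manifest data.frame with columns `id`, `image`, `split`.
#' @slot pathology binary matrix, 10 columns.
#' @slot location binary matrix, 9 columns.
#' @slot text data.frame of sign-attribute values (one column per schema
#'   attribute).
#' @slot images list of `(3,S,S)` arrays (may be empty; loaded lazily).
#' @slot dir dataset directory on disk ("" for purely in-memory sets).
#' @slot config the generator configuration used (list; may be empty).
#' @export
setClass("TongueDataset",
         representation(manifest = "data.frame", pathology = "matrix",
                        location = "matrix", text = "data.frame",
                        images = "list", dir = "character",
                        config = "list"))

setValidity("TongueDataset", function(object) {
  n <- nrow(object@manifest)
  msgs <- character(0)
  if (ncol(object@pathology) != 10L) msgs <- c(msgs, "pathology must have 10 columns")
  if (ncol(object@location) != 9L) msgs <- c(msgs, "location must have 9 columns")
  if (nrow(object@pathology) != n || nrow(object@location) != n ||
      nrow(object@text) != n)
    msgs <- c(msgs, "manifest, labels and text must have equal row counts")
  if (!all(object@manifest$split %in% c("train", "val", "test")))
    msgs <- c(msgs, "split tags must be train/val/test")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TongueDataset", function(object) {
  tab <- table(object@manifest$split)
  cat("TongueDataset with", nrow(object@manifest), "samples",
      sprintf("(train %d / val %d / test %d)\n",
              tab[["train"]] %||% 0L, tab[["val"]] %||% 0L, tab[["test"]] %||% 0L))
  cat("  pathology labels:", paste(colnames(object@pathology), collapse = ", "), "\n")
  cat("  location labels: ", paste(colnames(object@location), collapse = ", "), "\n")
  cat("  images:", if (length(object@images)) "in memory" else
    paste0("on disk (", object@dir, ")"), "\n")
})

`%||%` <- function(a, b)
  tryCatch({ v <- a; if (is.null(v)) b else v }, error = function(e) b)

#' @describeIn TongueDataset the sample manifest.
#' @param x a TongueDataset.
#' @export
manifest <- function(x) x@manifest

#' @describeIn TongueDataset binary target matrix for one task.
#' @param task `"pathology"` or `"location"`.
#' @export
labelMatrix <- function(x, task = c("pathology", "location")) {
  task <- match.arg(task)
  slot(x, task)
}

#' @describeIn TongueDataset the text records (data.frame).
#' @export
textRecords <- function(x) x@text

#' @describeIn TongueDataset row indices of one split.
#' @param split `"train"`, `"val"` or `"test"`.
#' @export
splitIdx <- function(x, split) which(x@manifest$split == split)

#' @describeIn TongueDataset image arrays (loading from disk if needed).
#' @param idx row indices (default all).
#' @export
datasetImages <- function(x, idx = seq_len(nrow(x@manifest))) {
  if (length(x@images)) return(x@images[idx])
  lapply(x@manifest$image[idx], function(p) {
    img <- png::readPNG(file.path(x@dir, p))
    aperm(img, c(3, 1, 2))
  })
}

#' Build a synthetic dataset
#'
#' Draws labels, renders images and text records, assigns splits by the
#' configured fractions (counts are `round(f * n)` for train and val, the
#' remainder is test), and optionally writes PNG images plus a JSON-Lines
#' manifest to `out_dir`. Fully reproducible from `cfg$seed`.
#'
#' @param cfg configuration from [generatorConfig()].
#' @param out_dir output directory, or `NULL` for an in-memory dataset.
#' @return A [TongueDataset-class] (images kept in memory either way).
#' @export
buildDataset <- function(cfg, out_dir = NULL) {
  n <- cfg$n_samples
  set.seed(cfg$seed)
  if (cfg$joint_signal) {
    img_bit <- stats::rbinom(n, 1L, 0.5)
    img_cues <- matrix(img_bit, n, 19L)
    txt_cues <- matrix(stats::rbinom(n * 19L, 1L, 0.5), n, 19L)
    bits <- (img_cues + txt_cues) %% 2L
    pat <- bits[, 1:10, drop = FALSE]
    loc <- bits[, 11:19, drop = FALSE]
    colnames(pat) <- pathologyLabels(); colnames(loc) <- locationLabels()
    labels <- list(pathology = pat, location = loc)
  } else {
    labels <- sampleLabels(cfg, n)
    img_cues <- txt_cues <- NULL
  }
  n_train <- round(cfg$split_fractions[1] * n)
  n_val <- round(cfg$split_fractions[2] * n)
  perm <- sample.int(n)
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[split == ""] <- "test"
  images <- vector("list", n)
  texts <- vector("list", n)
  for (i in seq_len(n)) {
    sd_i <- (cfg$seed + 7919L * i) %% .Machine$integer.max
    images[[i]] <- renderImage(labels$pathology[i, ], labels$location[i, ],
                               cfg, seed = sd_i,
                               image_cues = if (is.null(img_cues)) NULL else img_cues[i, ])
    texts[[i]] <- renderText(labels$pathology[i, ], labels$location[i, ],
                             cfg, seed = sd_i + 1L,
                             text_cues = if (is.null(txt_cues)) NULL else txt_cues[i, ])
  }
  text_df <- as.data.frame(do.call(rbind, texts), stringsAsFactors = FALSE)
  man <- data.frame(id = seq_len(n),
                    image = sprintf("images/sample_%04d.png", seq_len(n)),
                    split = split, stringsAsFactors = FALSE)
  dir_out <- ""
  if (!is.null(out_dir)) {
    dir_out <- out_dir
    ok <- dir.create(file.path(out_dir, "images"), recursive = TRUE,
                     showWarnings = FALSE)
    if (!dir.exists(file.path(out_dir, "images")))
      stop("cannot create output directory ", out_dir)
    for (i in seq_len(n))
      png::writePNG(aperm(images[[i]], c(2, 3, 1)),
                    file.path(out_dir, man$image[i]))
    con <- file(file.path(out_dir, "manifest.jsonl"), "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      rec <- list(id = man$id[i], image = man$image[i],
                  text = as.list(text_df[i, , drop = FALSE]),
                  pathology = unname(labels$pathology[i, ]),
                  location = unname(labels$location[i, ]),
                  split = man$split[i])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
    cfg_out <- cfg; class(cfg_out) <- NULL
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  new("TongueDataset", manifest = man, pathology = labels$pathology,
      location = labels$location, text = text_df, images = images,
      dir = dir_out, config = unclass(cfg))
}

#' Read a dataset written by [buildDataset()]
#'
#' @param dir dataset directory containing `manifest.jsonl` and `images/`.
#' @param load_images decode PNGs into memory (default TRUE).
#' @return A [TongueDataset-class].
#' @export
readDataset <- function(dir, load_images = TRUE) {
  path <- file.path(dir, "manifest.jsonl")
  if (!file.exists(path)) stop("no manifest.jsonl under ", dir)
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  n <- length(recs)
  pat <- do.call(rbind, lapply(recs, function(r) as.integer(r$pathology)))
  loc <- do.call(rbind, lapply(recs, function(r) as.integer(r$location)))
  colnames(pat) <- pathologyLabels(); colnames(loc) <- locationLabels()
  text_df <- as.data.frame(do.call(rbind, lapply(recs, function(r)
    unlist(r$text))), stringsAsFactors = FALSE)
  man <- data.frame(id = vapply(recs, function(r) as.integer(r$id), integer(1)),
                    image = vapply(recs, function(r) r$image, character(1)),
                    split = vapply(recs, function(r) r$split, character(1)),
                    stringsAsFactors = FALSE)
  imgs <- list()
  if (load_images)
    imgs <- lapply(man$image, function(p)
      aperm(png::readPNG(file.path(dir, p)), c(3, 1, 2)))
  cfg_path <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_path)) jsonlite::fromJSON(cfg_path) else list()
  new("TongueDataset", manifest = man, pathology = pat, location = loc,
      text = text_df, images = imgs, dir = dir, config = cfg)
}
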