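# Structured-text encoder.
#
# Tongue descriptions are expert annotation records over a fixed schema of
# categorical sign attributes (body colour signs, coating signs, regional
# signs), not free prose. Each attribute is embedded, embeddings are
# concatenated and passed through a two-layer perceptron with dropout to a
# d-dimensional Euclidean embedding matching the image embedding.

#' Default tongue-sign attribute schema
#'
#' One categorical attribute per observable sign. Every attribute carries an
#' explicit `"UNK"` value for unseen/unknown entries. Pathology signs mirror
#' classic TCM tongue findings (red body for heat, pale body for blood
#' deficiency, teeth marks for Qi deficiency, ...); regional signs follow
#' the tongue region-to-organ map (tip = heart/lung, sides = liver,
#' centre = spleen/stomach, root = kidney/intestine).
#'
#' @return Named list: attribute name -> character vector of levels
#'   (first level is the default), with `"UNK"` appended.
#' @export
textSchema <- function() {
  sign <- c("absent", "present")
  sch <- list(
    pale_blue_body   = sign,  # cold
    teeth_marks      = sign,  # Qi deficiency
    curled_edges     = sign,  # Qi stagnation
    red_body         = sign,  # heat
    greasy_coating   = sign,  # dampness
    thick_coating    = sign,  # phlegm
    pale_body        = sign,  # blood deficiency
    purple_spots     = sign,  # blood stasis
    wet_swollen      = sign,  # Yang deficiency
    cracked_dry      = sign,  # Yin deficiency
    root_greasy      = sign,  # intestine
    tip_thin_white   = sign,  # lung
    side_red_marks   = sign,  # liver
    center_thick_coat = sign, # spleen
    center_yellow_coat = sign, # stomach
    root_dark_coat   = sign,  # kidney
    tip_red_points   = sign,  # heart
    diffuse_spots    = sign,  # others
    clean_pink       = sign   # healthy
  )
  lapply(sch, function(v) c(v, "UNK"))
}

#' Vectorize a text record against a schema
#'
#' Deterministic one-index-per-attribute encoding. Values not listed in the
#' schema map to the explicit `UNK` index; attributes missing from the
#' schema raise an error.
#'
#' @param rec named list or character vector of attribute values.
#' @param schema schema as returned by [textSchema()].
#' @return Integer vector, one 1-based level index per schema attribute
#'   (schema order).
#' @export
vectorizeText <- function(rec, schema = textSchema()) {
  rec <- as.list(rec)
  extra <- setdiff(names(rec), names(schema))
  if (length(extra))
    stop("attribute(s) absent from schema: ", paste(extra, collapse = ", "))
  idx <- integer(length(schema))
  names(idx) <- names(schema)
  for (j in seq_along(schema)) {
    nm <- names(schema)[j]
    lv <- schema[[j]]
    val <- if (!is.null(rec[[nm]])) as.character(rec[[nm]]) else lv[1]
    k <- match(val, lv)
    idx[j] <- if (is.na(k)) match("UNK", lv) else k
  }
  idx
}

#' Invert [vectorizeText()]
#' @param idx integer index vector.
#' @param schema schema as returned by [textSchema()].
#' @return Named character vector of attribute values.
#' @export
devectorizeText <- function(idx, schema = textSchema()) {
  stopifnot(length(idx) == length(schema))
  out <- vapply(seq_along(schema), function(j) schema[[j]][idx[j]], character(1))
  names(out) <- names(schema)
  out
}

text_init <- function(cfg, schema = textSchema()) {
  e <- cfg$attr_embed_dim
  tables <- lapply(schema, function(lv)
    ag_param(matrix(stats::rnorm(length(lv) * e, sd = 0.05), length(lv), e)))
  n_in <- length(schema) * e
  list(tables = tables,
       fc1 = new_linear(n_in, cfg$text_hidden),
       fc2 = new_linear(cfg$text_hidden, cfg$embed_dim),
       schema = schema, e = e)
}

text_params <- function(tx)
  c(tx$tables, list(tx$fc1$W, tx$fc1$b, tx$fc2$W, tx$fc2$b))

text_fwd <- function(tx, idx_mat, cfg, training = FALSE) {
  # idx_mat: (B, n_attr) integer matrix of level indices
  B <- nrow(idx_mat)
  n_attr <- length(tx$tables)
  embs <- vector("list", n_attr)
  for (j in seq_len(n_attr)) {
    tab <- tx$tables[[j]]
    nv <- nrow(tab$v); e <- ncol(tab$v)
    ii <- idx_mat[, j]
    if (any(ii < 1L | ii > nv)) stop("out-of-vocabulary index for attribute ",
                                     names(tx$schema)[j])
    # gather rows ii of the table -> (B, e)
    gidx <- as.integer(outer(ii, (seq_len(e) - 1L) * nv, "+"))
    embs[[j]] <- ag_gather(tab, gidx, out_dim = c(B, e))
  }
  h <- ag_concat_cols(embs)
  h <- ag_gelu(linear_fwd(tx$fc1, h))
  h <- ag_dropout(h, cfg$dropout, training)
  linear_fwd(tx$fc2, h)
}

#' Encode a text record to its Euclidean embedding
#'
#' Embeds each attribute level, concatenates, and applies a two-layer
#' perceptron. Deterministic in eval mode (dropout disabled).
#'
#' @param idx integer index vector from [vectorizeText()], or a matrix with
#'   one record per row.
#' @param params encoder parameters: list with `tables` (one embedding
#'   matrix per attribute), `W1`, `b1`, `W2`, `b2`.
#' @return Embedding vector (or matrix, one row per record).
#' @export
encodeText <- function(idx, params) {
  one <- is.null(dim(idx))
  idx_mat <- if (one) matrix(idx, 1) else idx
  tx <- list(
    tables = lapply(params$tables, ag_const),
    fc1 = list(W = ag_const(params$W1), b = ag_const(params$b1)),
    fc2 = list(W = ag_const(params$W2), b = ag_const(params$b2)),
    schema = if (is.null(params$schema)) textSchema() else params$schema
  )
  cfg <- list(dropout = 0)
  out <- ag_value(text_fwd(tx, idx_mat, cfg, training = FALSE))
  if (one) as.vector(out) else out
}
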