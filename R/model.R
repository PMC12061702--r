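# TongueModel: the full multimodal network and its forward pass.
#
# image -> HAN encoder -> Z_t (Euclidean d-vector)
# text  -> attribute embeddings + MLP -> Z_s
# bridge(concat) -> F -> three subspace projections -> per-subspace
# multi-scale attention on a grouped tile view -> sum + layernorm ->
# two stacked-KAN heads (pathology 10, location 9) -> sigmoid probabilities.
# Hyperbolic images of embeddings and predictions feed the consistency and
# complementarity losses only.

#' TongueModel
#'
#' S4 wrapper around the trained network: the parameter/net structure, the
#' run configuration, and the per-epoch training log.
#'
#' @slot net list of components with autodiff parameter tensors.
#' @slot config the `tongue_run_config` used for training.
#' @slot log data.frame of per-step training losses.
#' @slot val data.frame of periodic validation metrics (may be empty).
#' @export
setClass("TongueModel",
         representation(net = "list", config = "list", log = "data.frame",
                        val = "data.frame"))

setMethod("show", "TongueModel", function(object) {
  np <- sum(vapply(netParameters(object@net), function(p) length(p$v),
                   numeric(1)))
  cat("TongueModel:", object@config$modality, "modality,",
      format(np, big.mark = ","), "parameters\n")
  if (nrow(object@log))
    cat("  trained", nrow(object@log), "steps; final total loss",
        sprintf("%.4f", utils::tail(object@log$total, 1)), "\n")
})

#' @describeIn TongueModel the run configuration.
#' @param x a TongueModel.
#' @export
modelConfig <- function(x) x@config

#' @describeIn TongueModel the per-step training loss log.
#' @export
trainingLog <- function(x) x@log

net_init <- function(cfg, priors = NULL) {
  d <- cfg$embed_dim
  d_f <- cfg$fused_channels * cfg$tile^2
  Cg <- cfg$fused_channels %/% cfg$ema_groups
  list(
    han = if (cfg$modality != "text") han_init(cfg) else NULL,
    text = if (cfg$modality != "image") text_init(cfg) else NULL,
    bridge = new_linear(2L * d, d_f),
    proj = list(new_linear(d_f, d_f), new_linear(d_f, d_f),
                new_linear(d_f, d_f)),
    ema = list(ema_init(Cg), ema_init(Cg), ema_init(Cg)),
    kan_path = kan_head_init(d_f, c(cfg$kan_hidden, 10L),
                             prior_logits = priors$pathology),
    kan_loc = kan_head_init(d_f, c(cfg$kan_hidden, 9L),
                            prior_logits = priors$location),
    d_f = d_f
  )
}

netParameters <- function(net) {
  ps <- list()
  if (!is.null(net$han)) ps <- c(ps, han_params(net$han))
  if (!is.null(net$text)) ps <- c(ps, text_params(net$text))
  ps <- c(ps, list(net$bridge$W, net$bridge$b))
  for (pr in net$proj) ps <- c(ps, list(pr$W, pr$b))
  for (em in net$ema) ps <- c(ps, ema_params(em))
  c(ps, kan_head_params(net$kan_path), kan_head_params(net$kan_loc))
}

net_forward <- function(net, cfg, imgs, text_idx, training = FALSE) {
  # imgs: (B,3,H,W) array or NULL; text_idx: (B, n_attr) int matrix or NULL
  B <- if (!is.null(imgs)) dim(imgs)[1] else nrow(text_idx)
  d <- cfg$embed_dim
  Zt <- if (cfg$modality != "text") han_fwd(net$han, ag_const(imgs), cfg)
        else ag_const(matrix(0, B, d))
  Zs <- if (cfg$modality != "image") text_fwd(net$text, text_idx, cfg, training)
        else ag_const(matrix(0, B, d))
  h <- ag_gelu(linear_fwd(net$bridge,
                          ag_concat_cols(list(ag_layernorm_rows(Zt),
                                              ag_layernorm_rows(Zs)))))
  h <- ag_dropout(h, cfg$dropout, training)
  C <- cfg$fused_channels; t_ <- cfg$tile; G <- cfg$ema_groups
  sub_out <- vector("list", 3L)
  for (k in 1:3) {
    Fk <- linear_fwd(net$proj[[k]], h)
    Fs <- ag_reshape(Fk, c(B, C, t_, t_))
    Fg <- fold_groups(Fs, G)
    Fw <- unfold_groups(ema_fwd(net$ema[[k]], Fg), G, c(B, C, t_, t_))
    sub_out[[k]] <- ag_reshape(Fw, c(B, C * t_ * t_))
  }
  Fprime <- ag_layernorm_rows(ag_add(ag_add(sub_out[[1]], sub_out[[2]]),
                                     sub_out[[3]]))
  logits_p <- kan_head_fwd(net$kan_path, Fprime)
  logits_l <- kan_head_fwd(net$kan_loc, Fprime)
  list(probs_pathology = ag_sigmoid(logits_p),
       probs_location = ag_sigmoid(logits_l),
       Zt = Zt, Zs = Zs)
}

net_loss <- function(net, cfg, fw, y_path, y_loc) {
  tasks <- switch(cfg$task, both = c("pathology", "location"),
                  pathology = "pathology", location = "location")
  l_ce <- NULL; l_compl <- NULL
  for (tk in tasks) {
    probs <- fw[[paste0("probs_", tk)]]
    tgt <- if (tk == "pathology") y_path else y_loc
    ce_k <- ag_bce_loss(probs, tgt)
    l_ce <- if (is.null(l_ce)) ce_k else ag_add(l_ce, ce_k)
    if (cfg$complementarity_enabled &&
        cfg$loss_weights[["w_compl"]] > 0) {
      cp_k <- ag_complementarity_loss(probs, tgt, cfg$curvature, cfg$ball_eps)
      l_compl <- if (is.null(l_compl)) cp_k else ag_add(l_compl, cp_k)
    }
  }
  l_ce <- ag_scale(l_ce, 1 / length(tasks))
  if (!is.null(l_compl)) l_compl <- ag_scale(l_compl, 1 / length(tasks))
  l_consis <- NULL
  if (cfg$consistency_enabled && cfg$loss_weights[["w_consis"]] > 0 &&
      cfg$modality == "both") {
    c_ <- cfg$curvature
    d_es <- ag_euclidean_distance(fw$Zt, fw$Zs)
    Zt_h <- ag_clip_ball(ag_expmap0(fw$Zt, c_), c_, cfg$ball_eps)
    Zs_h <- ag_clip_ball(ag_expmap0(fw$Zs, c_), c_, cfg$ball_eps)
    d_hs <- ag_hyperbolic_distance(Zt_h, Zs_h, c_)
    l_consis <- ag_consistency_loss(d_es, d_hs, cfg$consistency_denominator)
  }
  w <- cfg$loss_weights
  total <- ag_scale(l_ce, w[["w_ce"]])
  if (!is.null(l_consis)) total <- ag_add(total, ag_scale(l_consis, w[["w_consis"]]))
  if (!is.null(l_compl)) total <- ag_add(total, ag_scale(l_compl, w[["w_compl"]]))
  list(total = total, ce = l_ce, consis = l_consis, compl = l_compl)
}

batch_tensors <- function(ds, idx, cfg, schema_idx = NULL) {
  imgs <- NULL; text_idx <- NULL
  if (cfg$modality != "text") {
    il <- datasetImages(ds, idx)
    S <- dim(il[[1]])[2]
    imgs <- array(0, c(length(idx), 3, S, S))
    for (j in seq_along(il)) imgs[j, , , ] <- il[[j]]
  }
  if (cfg$modality != "image") {
    if (is.null(schema_idx)) schema_idx <- dataset_text_indices(ds)
    text_idx <- schema_idx[idx, , drop = FALSE]
  }
  list(imgs = imgs, text_idx = text_idx,
       y_path = labelMatrix(ds, "pathology")[idx, , drop = FALSE],
       y_loc = labelMatrix(ds, "location")[idx, , drop = FALSE])
}

dataset_text_indices <- function(ds) {
  schema <- textSchema()
  txt <- textRecords(ds)
  out <- matrix(1L, nrow(txt), length(schema))
  for (j in seq_along(schema)) {
    nm <- names(schema)[j]
    vals <- if (nm %in% names(txt)) as.character(txt[[nm]]) else
      rep(schema[[j]][1], nrow(txt))
    k <- match(vals, schema[[j]])
    k[is.na(k)] <- match("UNK", schema[[j]])
    out[, j] <- k
  }
  out
}

#' Predict label probabilities
#'
#' Runs the network in eval mode over the given samples.
#'
#' @param model a [TongueModel-class].
#' @param ds a [TongueDataset-class].
#' @param idx row indices (default all).
#' @param batch_size forward batch size.
#' @return List of matrices `pathology` (n x 10) and `location` (n x 9).
#' @export
predictModel <- function(model, ds, idx = seq_len(nrow(manifest(ds))),
                         batch_size = 64L) {
  cfg <- model@config
  sidx <- if (cfg$modality != "image") dataset_text_indices(ds) else NULL
  out_p <- matrix(NA_real_, length(idx), 10L)
  out_l <- matrix(NA_real_, length(idx), 9L)
  pos <- 1L
  while (pos <= length(idx)) {
    take <- idx[pos:min(pos + batch_size - 1L, length(idx))]
    bt <- batch_tensors(ds, take, cfg, sidx)
    fw <- net_forward(model@net, cfg, bt$imgs, bt$text_idx, training = FALSE)
    rows <- pos:(pos + length(take) - 1L)
    out_p[rows, ] <- ag_value(fw$probs_pathology)
    out_l[rows, ] <- ag_value(fw$probs_location)
    pos <- pos + length(take)
  }
  colnames(out_p) <- pathologyLabels(); colnames(out_l) <- locationLabels()
  list(pathology = out_p, location = out_l)
}
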