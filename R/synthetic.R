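# Synthetic tongue image/text dataset generator.
#
# Emulates the structure of an expert-annotated tongue-diagnosis dataset:
# label-conditional tongue-like images (an ellipse body whose colour,
# coating and regional texture depend on the active labels), paired
# structured text records whose sign attributes agree with the labels with
# a configurable probability, multi-label co-occurrence, and simulated
# three-annotator labelling noise. Everything is seeded and byte-level
# reproducible.

#' Pathology and location label names
#' @return Character vector of the 10 disease-nature labels
#'   (`pathologyLabels`) or the 9 disease-location labels
#'   (`locationLabels`).
#' @export
pathologyLabels <- function() c(
  "cold", "qi_deficiency", "qi_stagnation", "heat", "dampness", "phlegm",
  "blood_deficiency", "blood_stasis", "yang_deficiency", "yin_deficiency")

#' @rdname pathologyLabels
#' @export
locationLabels <- function() c(
  "intestine", "lung", "liver", "spleen", "kidney", "stomach", "heart",
  "others", "healthy")

#' Generator configuration
#'
#' @param n_samples number of samples.
#' @param split_fractions train/val/test fractions summing to 1.
#' @param image_size image side length in pixels (square RGB).
#' @param pathology_prevalence length-10 vector of per-label Bernoulli
#'   rates in (0,1).
#' @param location_prevalence length-9 vector (last entry is `healthy`).
#' @param effect_size strength of the label-conditional appearance signal;
#'   0 disables it, the per-region colour shift is `0.08 * effect_size`
#'   (capped at 0.4) on a [0,1] intensity scale.
#' @param cross_modal_agreement probability in `[0,1]` that a text sign
#'   attribute takes the value its label implies; otherwise a different
#'   level is drawn uniformly (1 = deterministic; 1/k = independent of the
#'   label for a k-level attribute).
#' @param annotator_error_rate per-label, per-annotator bit-flip rate in
#'   `[0,1)`.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param joint_signal if `TRUE`, generate the constructed joint-signal
#'   regime: every label k is the XOR of one hidden per-sample image cue
#'   bit (rendered as a bright central patch) and a per-label hidden text
#'   cue bit, so neither modality alone is informative but the pair is
#'   decisive.
#' @param seed integer RNG seed.
#' @return A `tongue_generator_config` list.
#' @export
generatorConfig <- function(n_samples = 400L,
                            split_fractions = c(0.70, 0.15, 0.15),
                            image_size = 64L,
                            pathology_prevalence = rep(0.30, 10),
                            location_prevalence = c(rep(0.25, 8), 0.15),
                            effect_size = 1,
                            cross_modal_agreement = 0.9,
                            annotator_error_rate = 0.05,
                            noise_sd = 0.05,
                            joint_signal = FALSE,
                            seed = 1L) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8,
            length(pathology_prevalence) == 10L,
            length(location_prevalence) == 9L,
            all(pathology_prevalence > 0 & pathology_prevalence < 1) ||
              all(pathology_prevalence >= 0),
            cross_modal_agreement >= 0, cross_modal_agreement <= 1,
            annotator_error_rate >= 0, annotator_error_rate < 1,
            image_size >= 16L)
  structure(list(n_samples = as.integer(n_samples),
                 split_fractions = split_fractions,
                 image_size = as.integer(image_size),
                 pathology_prevalence = pathology_prevalence,
                 location_prevalence = location_prevalence,
                 effect_size = effect_size,
                 cross_modal_agreement = cross_modal_agreement,
                 annotator_error_rate = annotator_error_rate,
                 noise_sd = noise_sd,
                 joint_signal = isTRUE(joint_signal),
                 seed = as.integer(seed)),
            class = "tongue_generator_config")
}

#' Sample multi-label targets
#'
#' Independent Bernoulli draws per label at the configured prevalences; a
#' sample with `healthy = 1` has all pathology bits forced to 0.
#'
#' @param cfg generator configuration.
#' @param n number of samples (defaults to `cfg$n_samples`).
#' @return List with binary matrices `pathology` (n x 10) and `location`
#'   (n x 9); column names are the label names.
#' @export
sampleLabels <- function(cfg, n = cfg$n_samples) {
  loc <- matrix(stats::rbinom(n * 9L, 1L, rep(cfg$location_prevalence,
                                              each = n)), n, 9L)
  pat <- matrix(stats::rbinom(n * 10L, 1L, rep(cfg$pathology_prevalence,
                                               each = n)), n, 10L)
  healthy <- loc[, 9L] == 1L
  pat[healthy, ] <- 0L
  colnames(pat) <- pathologyLabels()
  colnames(loc) <- locationLabels()
  list(pathology = pat, location = loc)
}

# region masks on an S x S grid; x: columns, y: rows (row 1 = tongue root)
tongue_regions <- function(S) {
  xs <- matrix(rep((seq_len(S) - 0.5) / S, each = S), S, S)   # column coord
  ys <- matrix(rep((seq_len(S) - 0.5) / S, times = S), S, S)  # row coord
  body <- ((xs - 0.5) / 0.34)^2 + ((ys - 0.52) / 0.44)^2 <= 1
  list(
    body = body,
    center = body & ((xs - 0.5) / 0.16)^2 + ((ys - 0.5) / 0.18)^2 <= 1,
    tip = body & ys > 0.72,
    root = body & ys < 0.32,
    sides = body & abs(xs - 0.5) > 0.22,
    edge = body & (((xs - 0.5) / 0.34)^2 + ((ys - 0.52) / 0.44)^2 > 0.72),
    xs = xs, ys = ys
  )
}

#' Render a label-conditional tongue image
#'
#' Draws an elliptical tongue body on a dark background and applies
#' label-conditional colour/coating/regional-texture shifts (e.g. heat
#' reddens the body, dampness brightens a central coating patch, each organ
#' label textures its tongue region), then adds Gaussian pixel noise.
#' Deterministic given `(pathology, location, seed)`.
#'
#' @param pathology binary vector of length 10.
#' @param location binary vector of length 9.
#' @param cfg generator configuration.
#' @param seed integer seed for the pixel noise (and dot placement).
#' @param image_cues optional binary vector of length 19 for the
#'   joint-signal regime (overrides label-conditional rendering with cue
#'   patches).
#' @return Array `(3, S, S)` with values in `[0, 1]`.
#' @export
renderImage <- function(pathology, location, cfg, seed = cfg$seed,
                        image_cues = NULL) {
  S <- cfg$image_size
  a <- min(0.08 * cfg$effect_size, 0.4)
  rg <- tongue_regions(S)
  R <- matrix(0.15, S, S); G <- matrix(0.15, S, S); B <- matrix(0.15, S, S)
  R[rg$body] <- 0.78; G[rg$body] <- 0.52; B[rg$body] <- 0.52
  set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(image_cues)) {
    p <- as.numeric(pathology); l <- as.numeric(location)
    if (p[1]) { R[rg$body] <- R[rg$body] - 0.5 * a; B[rg$body] <- B[rg$body] + a }          # cold
    if (p[2]) { R[rg$edge] <- R[rg$edge] + a; G[rg$edge] <- G[rg$edge] + a }               # qi def: pale edge
    if (p[3]) { m <- rg$sides & rg$ys > 0.4 & rg$ys < 0.7; G[m] <- G[m] - a }              # qi stagnation
    if (p[4]) R[rg$body] <- R[rg$body] + a                                                  # heat
    if (p[5]) { R[rg$center] <- R[rg$center] + a; G[rg$center] <- G[rg$center] + a
                B[rg$center] <- B[rg$center] + a }                                          # dampness coating
    if (p[6]) { G[rg$center] <- G[rg$center] + a; B[rg$center] <- B[rg$center] + 0.7 * a }  # phlegm
    if (p[7]) { R[rg$body] <- R[rg$body] - 0.4 * a; G[rg$body] <- G[rg$body] + 0.6 * a }    # blood def: pale
    if (p[8]) {                                                                             # blood stasis dots
      ii <- which(rg$body)
      dots <- ii[1 + (seq_len(12) * 977L) %% length(ii)]
      R[dots] <- R[dots] - 0.3 * a; B[dots] <- B[dots] + 2 * a
    }
    if (p[9]) { m <- rg$body & rg$ys > 0.55 & rg$ys < 0.65; B[m] <- B[m] + a }              # yang def
    if (p[10]) { m <- rg$body & abs(rg$xs - 0.5) < 0.02; R[m] <- R[m] - a; G[m] <- G[m] - a } # yin def cracks
    if (l[1]) B[rg$root] <- B[rg$root] + a                                                  # intestine
    if (l[2]) G[rg$tip] <- G[rg$tip] + a                                                    # lung
    if (l[3]) { m <- rg$sides; R[m] <- R[m] + a; B[m] <- B[m] - 0.3 * a }                   # liver
    if (l[4]) { m <- rg$center & rg$ys < 0.5; R[m] <- R[m] + 0.7 * a; G[m] <- G[m] + a }    # spleen
    if (l[5]) { m <- rg$center & rg$ys >= 0.5; R[m] <- R[m] + 0.6 * a
                G[m] <- G[m] + 0.6 * a; B[m] <- B[m] - 0.3 * a }                            # stomach
    if (l[6]) { R[rg$root] <- R[rg$root] - a; G[rg$root] <- G[rg$root] - 0.7 * a }          # kidney
    if (l[7]) R[rg$tip] <- R[rg$tip] + a                                                    # heart
    if (l[8]) { m <- rg$body & ((rg$xs * S) %% 8 < 1.5) & ((rg$ys * S) %% 8 < 1.5)
                G[m] <- G[m] + a }                                                          # others
    # healthy: absence of any texture
  } else {
    # joint-signal regime: one shared cue bit, rendered as a bright central
    # patch when set
    if (image_cues[1] == 1) {
      m <- abs(rg$xs - 0.5) < 0.2 & abs(rg$ys - 0.5) < 0.2
      G[m] <- G[m] + 0.3; B[m] <- B[m] + 0.3
    }
  }
  noise <- array(stats::rnorm(3 * S * S, sd = cfg$noise_sd), c(3, S, S))
  img <- array(0, c(3, S, S))
  img[1, , ] <- R; img[2, , ] <- G; img[3, , ] <- B
  img <- img + noise
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Render a label-conditional text record
#'
#' Each sign attribute takes the value implied by its label with probability
#' `cross_modal_agreement`, otherwise a uniformly random level; at
#' agreement 1 the record is a deterministic function of the labels, at
#' agreement 1/k it is independent of them.
#'
#' @param pathology,location binary label vectors (10 and 9).
#' @param cfg generator configuration.
#' @param seed integer seed.
#' @param text_cues optional binary vector of length 19 (joint-signal
#'   regime: attributes encode the hidden text cue bits instead).
#' @return Named character vector over [textSchema()] attributes.
#' @export
renderText <- function(pathology, location, cfg, seed = cfg$seed,
                       text_cues = NULL) {
  schema <- textSchema()
  bits <- if (is.null(text_cues)) c(as.numeric(pathology), as.numeric(location))
          else as.numeric(text_cues)
  stopifnot(length(bits) == length(schema))
  set.seed(as.integer(seed %% .Machine$integer.max))
  vals <- character(length(schema))
  for (j in seq_along(schema)) {
    lv <- setdiff(schema[[j]], "UNK")
    implied <- lv[1 + bits[j]]            # absent/present
    vals[j] <- if (stats::runif(1) < cfg$cross_modal_agreement) implied
               else sample(setdiff(lv, implied), 1L)
  }
  names(vals) <- names(schema)
  vals
}

#' Simulate three independent annotators
#'
#' Each annotator independently flips each true label bit with probability
#' `error_rate`.
#'
#' @param truth binary matrix (samples x labels).
#' @param error_rate flip probability in `[0, 1)`.
#' @param seed integer seed.
#' @return List of three matrices `a1`, `a2`, `a3`.
#' @export
simulateAnnotators <- function(truth, error_rate, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1)
  truth <- as.matrix(truth)
  set.seed(as.integer(seed))
  flip <- function() {
    f <- matrix(stats::rbinom(length(truth), 1L, error_rate), nrow(truth))
    (truth + f) %% 2L
  }
  list(a1 = flip(), a2 = flip(), a3 = flip())
}

#' Exact unanimity probability under annotator noise
#'
#' Probability that three independent annotators, each flipping every one of
#' `L` bits with rate `e`, produce three identical label vectors: per bit
#' the three observed bits agree iff all three are unflipped or all three
#' flipped, so \eqn{P = ((1-e)^3 + e^3)^L}.
#'
#' @param error_rate flip rate.
#' @param n_labels number of labels L.
#' @return Retention probability.
#' @export
unanimityProbability <- function(error_rate, n_labels) {
  ((1 - error_rate)^3 + error_rate^3)^n_labels
}
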