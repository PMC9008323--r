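## ---------------------------------------------------------------------------
## Image pipeline: latency-coded digits -> unsupervised winner-take-all
## feature layer -> ALSA-supervised readout, plus loaders and a synthetic
## glyph generator so the pipeline can be exercised without any download.
## ---------------------------------------------------------------------------

## 7x5 bitmap font for digits 0-9 (rows top to bottom)
.glyphs <- local({
  g <- c(
    "01110 10001 10011 10101 11001 10001 01110",  # 0
    "00100 01100 00100 00100 00100 00100 01110",  # 1
    "01110 10001 00001 00010 00100 01000 11111",  # 2
    "11111 00010 00100 00010 00001 10001 01110",  # 3
    "00010 00110 01010 10010 11111 00010 00010",  # 4
    "11111 10000 11110 00001 00001 10001 01110",  # 5
    "00110 01000 10000 11110 10001 10001 01110",  # 6
    "11111 00001 00010 00100 01000 01000 01000",  # 7
    "01110 10001 10001 01110 10001 10001 01110",  # 8
    "01110 10001 10001 01111 00001 00010 01100")  # 9
  lapply(g, function(s) {
    rows <- strsplit(s, " ")[[1]]
    do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]])))
  })
})

#' Synthetic handwritten-digit stand-in images
#'
#' Generates grayscale digit images from fixed 7x5 glyph bitmaps,
#' upscaled and placed with random integer jitter, with multiplicative
#' intensity variation on the strokes and additive background noise.
#' They emulate the geometry of scanned-digit data (bright strokes on a
#' dark background, class-consistent shape, positional jitter) but not
#' its full handwriting variability; filenames and docs label them
#' synthetic throughout.
#'
#' @param n number of images.
#' @param size image side length in pixels.
#' @param scale integer upscaling factor of the 7x5 glyph.
#' @param jitter maximum absolute random shift, pixels.
#' @param noise background noise level (uniform on \code{[0, noise]});
#'   stroke intensity is drawn from \code{[1 - noise, 1]}.
#' @param classes digit classes to draw from (0-9).
#' @param seed integer seed.
#' @return list with \code{images} (list of size x size matrices in
#'   \eqn{[0,1]}) and \code{labels} (integer digits).
#' @export
synthetic_digit_images <- function(n, size = 28, scale = 3, jitter = 2,
                                   noise = 0.1, classes = 0:9, seed = 1L) {
  set.seed(seed)
  labels <- sample(classes, n, replace = TRUE)
  up <- matrix(1, scale, scale)
  images <- lapply(labels, function(d) {
    glyph <- kronecker(.glyphs[[d + 1L]], up)
    img <- matrix(stats::runif(size * size, 0, noise), size, size)
    r0 <- floor((size - nrow(glyph)) / 2) + sample(-jitter:jitter, 1)
    c0 <- floor((size - ncol(glyph)) / 2) + sample(-jitter:jitter, 1)
    rows <- r0 + seq_len(nrow(glyph)); cols <- c0 + seq_len(ncol(glyph))
    ok_r <- rows >= 1 & rows <= size; ok_c <- cols >= 1 & cols <= size
    sub <- glyph[ok_r, ok_c, drop = FALSE] *
      matrix(stats::runif(sum(ok_r) * sum(ok_c), 1 - noise, 1),
             sum(ok_r), sum(ok_c))
    tgt <- img[rows[ok_r], cols[ok_c], drop = FALSE]
    img[rows[ok_r], cols[ok_c]] <- pmax(tgt, sub)
    img
  })
  list(images = images, labels = labels)
}

#' Read an IDX-format image or label archive
#'
#' Parses the big-endian IDX container used for handwritten-digit
#' archives: a magic number (data type and dimension count), the
#' dimension sizes, then the raw data. Unsigned-byte payloads (the usual
#' case) are supported.
#'
#' @param path file path (uncompressed IDX).
#' @return for 1-d archives an integer vector (labels); for 3-d archives
#'   a list of matrices (images scaled to \eqn{[0,1]}).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  dtype <- bitwAnd(bitwShiftR(magic, 8), 0xFF)
  ndim <- bitwAnd(magic, 0xFF)
  if (dtype != 0x08) stop("only unsigned-byte IDX archives are supported")
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  data <- as.integer(readBin(con, "raw", prod(dims)))
  if (ndim == 1L) return(data)
  if (ndim == 3L) {
    npix <- dims[2] * dims[3]
    return(lapply(seq_len(dims[1]), function(i) {
      m <- matrix(data[(i - 1L) * npix + seq_len(npix)],
                  dims[2], dims[3], byrow = TRUE)
      m / 255
    }))
  }
  stop("unsupported IDX dimensionality: ", ndim)
}

#' Read images from a labelled CSV table
#'
#' Expects one row per image: the label in the first column, then the
#' flattened pixels (row-major). Pixel values above 1 are assumed 8-bit
#' and divided by 255.
#'
#' @param path CSV file path.
#' @param size image side length.
#' @return list with \code{images} and \code{labels} as in
#'   \code{\link{synthetic_digit_images}}.
#' @export
digits_from_csv <- function(path, size = 28) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  labels <- as.integer(m[, 1])
  px <- m[, -1, drop = FALSE]
  if (max(px) > 1) px <- px / 255
  images <- lapply(seq_len(nrow(px)), function(i)
    matrix(px[i, ], size, size, byrow = TRUE))
  list(images = images, labels = labels)
}

#' Mean stroke contrast of learned receptive fields
#'
#' For each postsynaptic neuron of a projection, the contrast of its
#' incoming weight column is measured as the difference between the mean
#' of the top decile and the overall mean, normalised by the overall
#' mean. Receptive fields that imprint a sample pattern have high
#' contrast; uniform random weights have contrast near the value set by
#' the initialisation range.
#'
#' @param net a \code{snn_network}.
#' @param proj projection name, e.g. \code{"input->features"}.
#' @return mean contrast over postsynaptic neurons.
#' @export
weight_contrast <- function(net, proj) {
  w <- net$projections[[proj]]$w
  mean(apply(w, 2, function(col) {
    top <- mean(sort(col, decreasing = TRUE)[seq_len(max(1, length(col) %/% 10))])
    (top - mean(col)) / (mean(col) + 1e-12)
  }))
}

#' Layer-wise digit classification pipeline
#'
#' Latency-encodes grayscale images, trains a winner-take-all feature
#' layer (lateral inhibition + adaptive thresholds) with the unsupervised
#' plasticity rule, freezes it, then trains a feature -> output readout
#' with the teacher layer (ALSA), and evaluates on held-out images.
#' Defaults follow the reference digit network (28 x 28 inputs, encoding
#' threshold 0.3, input->feature weights U(0.01, 0.11) with eta = 0.015,
#' alpha = -0.3, beta = 1.3, tau_p = 20; feature->output weights
#' U(0.1, 0.2) with eta = 0.001, alpha = -0.003, beta = 2, tau_p = 100;
#' 20 Hz teacher; 200 ms presentations with 50 ms gaps). At desk scale
#' (hundreds of training images instead of tens of thousands) the two
#' learning rates can be raised via \code{eta_unsup} / \code{eta_sup}.
#'
#' @param images,labels training images (list of matrices in
#'   \eqn{[0,1]}) and integer labels.
#' @param test_images,test_labels held-out set.
#' @param n_features feature-layer size.
#' @param limit optional cap on the number of training images used.
#' @param unsup_epochs,sup_epochs passes for the two phases.
#' @param encode a \code{\link{latency_code}}.
#' @param eta_unsup,alpha_unsup,beta_unsup,tau_p_unsup input->feature
#'   plasticity constants.
#' @param eta_sup,alpha_sup,beta_sup,tau_p_sup feature->output plasticity
#'   constants.
#' @param init_unsup,init_sup weight-initialisation ranges.
#' @param normalize_input if \code{TRUE} the input->feature columns are
#'   divisively renormalised to their initial total after every update
#'   (norm-fair template competition, as in winner-take-all digit
#'   networks trained with spike-timing plasticity).
#' @param inhibition_weight frozen lateral-inhibition weight in the
#'   feature layer.
#' @param feature_params,output_params \code{\link{neuron_params}} of the
#'   two LIF layers.
#' @param teacher_rate,teacher_weight teacher drive.
#' @param t_present,t_gap presentation timing, ms.
#' @param dt simulation step, ms.
#' @param snapshot_every if not \code{NULL}, the input->feature weight
#'   contrast is recorded every this many unsupervised presentations.
#' @param seed root seed.
#' @return list with \code{accuracy}, \code{confusion}, \code{network},
#'   \code{feature_counts} (per-presentation feature spike counts during
#'   the unsupervised phase) and \code{contrast} (trajectory, or the
#'   initial/final pair).
#' @export
run_digits <- function(images, labels, test_images, test_labels,
                       n_features = 400, limit = NULL,
                       unsup_epochs = 1, sup_epochs = 1,
                       encode = latency_code(threshold = 0.3, window = 200,
                                             lead = 100, repeat_period = 25),
                       eta_unsup = 0.015, alpha_unsup = -0.3,
                       beta_unsup = 1.3, tau_p_unsup = 20,
                       eta_sup = 0.001, alpha_sup = -0.003,
                       beta_sup = 2, tau_p_sup = 100,
                       init_unsup = c(0.01, 0.11), init_sup = c(0.1, 0.2),
                       normalize_input = TRUE,
                       inhibition_weight = 5,
                       feature_params = neuron_params(V_thr_delta = 3,
                                                      tau_thr = 1e5,
                                                      tau_I = 20),
                       output_params = neuron_params(tau_E = 25,
                                                     V_thr_delta = 0.1,
                                                     tau_thr = 2000),
                       teacher_rate = 20, teacher_weight = 2,
                       t_present = 200, t_gap = 50, dt = 0.5,
                       snapshot_every = NULL, seed = 1L) {
  if (!is.null(limit)) {
    keep <- seq_len(min(limit, length(images)))
    images <- images[keep]; labels <- labels[keep]
  }
  classes <- sort(unique(c(labels, test_labels)))
  k <- length(classes)
  n_in <- length(images[[1]])
  as_samples <- function(imgs, labs) lapply(seq_along(imgs), function(i)
    list(stimulus = list(input = list(
           kind = "spikes", spikes = latency_spikes(imgs[[i]], encode))),
         label = match(labs[i], classes)))
  train_samples <- as_samples(images, labels)
  test_samples <- as_samples(test_images, test_labels)

  pp_u <- plasticity_params(eta_unsup, alpha_unsup, beta_unsup, tau_p_unsup)
  pp_s <- plasticity_params(eta_sup, alpha_sup, beta_sup, tau_p_sup)
  net <- build_network(
    list(layer("input", n_in, type = "source"),
         layer("features", n_features, feature_params),
         layer("output", k, output_params)),
    list(projection("input", "features", init_unsup, plasticity = pp_u,
                    normalize = if (normalize_input)
                      n_in * mean(init_unsup) else NULL),
         projection("features", "features",
                    matrix(inhibition_weight, n_features, n_features),
                    sign = "inhibitory"),
         projection("features", "output", init_sup, plasticity = pp_s)),
    dt = dt, seed = seed)

  ## phase 1: unsupervised feature learning (readout frozen meanwhile)
  net$projections[["features->output"]]$plasticity <- NULL
  proto_u <- training_protocol(t_present = t_present, t_gap = t_gap,
                               teacher_rate = 0, epochs = unsup_epochs,
                               seed = seed + 7L)
  contrast <- c(initial = weight_contrast(net, "input->features"))
  tu <- train_unsupervised(net, train_samples, proto_u,
                           record_layer = "features")
  net <- tu$network
  contrast <- c(contrast, final = weight_contrast(net, "input->features"))

  ## phase 2: freeze the feature weights; the adaptive thresholds stay
  ## live so the homeostatic winner rotation seen in training also governs
  ## readout training and evaluation
  net$projections[["input->features"]]$plasticity <- NULL
  net$projections[["features->output"]]$plasticity <- pp_s
  net <- attach_teacher(net, "output", k, weight = teacher_weight)
  proto_s <- training_protocol(t_present = t_present, t_gap = t_gap,
                               teacher_rate = teacher_rate,
                               epochs = sup_epochs, seed = seed + 11L)
  ts <- train_supervised(net, train_samples, proto_s)
  net <- ts$network

  ev <- evaluate_network(net, test_samples,
                         training_protocol(t_present = t_present,
                                           t_gap = t_gap, teacher_rate = 0,
                                           seed = seed + 13L))
  list(accuracy = ev$accuracy, confusion = ev$confusion,
       network = ev$network, feature_counts = tu$counts,
       contrast = contrast, classes = classes)
}
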