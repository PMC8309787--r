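# Synthetic orchard-pass generator: a camera moving along a row of static
# fruit, rendered as vertical image motion so every fruit traverses the
# frame top-to-bottom and crosses a horizontal ROI line; plus a
# detection-corruption model (flicker, occlusion episodes, localization
# jitter, false positives, confidence noise, appearance embeddings).

#' Scene configuration
#'
#' Defaults emulate a hand-held pass under a joint-tree pear row filmed in
#' portrait 1080x1920: ~25 fruit visible per frame, each fruit in view for
#' about 100 frames.
#'
#' @param n_fruits number of fruit along the strip (default 50).
#' @param frame_size `c(width, height)` pixels (default 1080 x 1920).
#' @param camera_speed pixels of image motion per frame (default 20).
#' @param fruit_size_range `c(min, max)` box size in pixels (default
#'   60-140).
#' @param strip_length world length of the tree-row strip in pixels
#'   (default 4000).
#' @param seed RNG seed; identical seeds give byte-identical scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_fruits = 50L, frame_size = c(1080, 1920),
                         camera_speed = 20, fruit_size_range = c(60, 140),
                         strip_length = 4000, seed = 1L) {
  stopifnot(n_fruits >= 0L, camera_speed > 0, all(fruit_size_range > 0),
            strip_length > 0, length(frame_size) == 2L, all(frame_size > 0))
  if (fruit_size_range[2L] > min(frame_size))
    stop("fruit larger than the frame", call. = FALSE)
  structure(list(n_fruits = as.integer(n_fruits),
                 frame_size = as.numeric(frame_size),
                 camera_speed = camera_speed,
                 fruit_size_range = as.numeric(fruit_size_range),
                 strip_length = strip_length, seed = as.integer(seed)),
            class = "scene_config")
}

#' Detection-corruption configuration
#'
#' @param p_miss per fruit-frame independent dropout (flicker) probability.
#' @param occlusion_rate expected occlusion episodes per fruit (Poisson).
#' @param occlusion_duration `c(min, max)` episode length in frames.
#' @param jitter_sigma localization jitter, pixels, on box centers
#'   (log-sizes are jittered with sd `jitter_sigma / height`).
#' @param fp_rate expected spurious detections per frame (Poisson).
#' @param confidence_model list with `true = c(mean, sd)` and
#'   `false = c(mean, sd)`; samples are clipped to \[0, 1\].
#' @param embedding_dim appearance-vector dimension (default 128, the
#'   convention of CNN re-identification embeddings; dimensions much lower
#'   than ~64 make random base vectors collide in cosine distance).
#' @param embedding_noise RMS norm of the Gaussian perturbation added to a
#'   fruit's unit base embedding before renormalization (per-coordinate sd
#'   is `embedding_noise / sqrt(embedding_dim)`), so 0.1 means the
#'   appearance vector wobbles by about 10% of its length regardless of
#'   dimension.
#' @param seed corruption RNG seed, independent of the scene seed. Flicker
#'   uniforms are drawn once per fruit-frame and compared against `p_miss`,
#'   so runs that share a seed but differ in `p_miss` are monotonically
#'   coupled: raising `p_miss` only ever removes detections.
#' @return A `corruption_config` list.
#' @export
corruption_config <- function(p_miss = 0.1, occlusion_rate = 1,
                              occlusion_duration = c(10, 45),
                              jitter_sigma = 2, fp_rate = 0.2,
                              confidence_model = list(true = c(0.85, 0.08),
                                                      false = c(0.4, 0.15)),
                              embedding_dim = 128L, embedding_noise = 0.1,
                              seed = 1L) {
  stopifnot(p_miss >= 0, p_miss <= 1, occlusion_rate >= 0,
            length(occlusion_duration) == 2L, all(occlusion_duration >= 1),
            jitter_sigma >= 0, fp_rate >= 0, embedding_dim >= 1L,
            embedding_noise >= 0)
  structure(list(p_miss = p_miss, occlusion_rate = occlusion_rate,
                 occlusion_duration = as.numeric(occlusion_duration),
                 jitter_sigma = jitter_sigma, fp_rate = fp_rate,
                 confidence_model = confidence_model,
                 embedding_dim = as.integer(embedding_dim),
                 embedding_noise = embedding_noise, seed = as.integer(seed)),
            class = "corruption_config")
}

unit_rows <- function(M) M / sqrt(rowSums(M^2))

#' Generate a synthetic orchard pass
#'
#' Fruits are placed uniformly at random along the strip and across the
#' frame width; the camera pans so the image content moves downward by
#' `camera_speed` pixels per frame. A fruit is visible while its box
#' intersects the viewport; visible boxes are clipped to the frame. The
#' ideal detection stream is the ground truth with confidence 1 and the
#' fruit's unit-norm base embedding attached.
#'
#' @param cfg a [scene_config].
#' @return List with `scene` (a [gt_scene]), `detections` (ideal stream,
#'   with `source_id` provenance), `fruits` (data.frame of world positions
#'   and sizes), `embeddings` (base matrix, one unit row per fruit) and
#'   `config`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  W <- cfg$frame_size[1L]; H <- cfg$frame_size[2L]
  L <- cfg$strip_length; s <- cfg$camera_speed
  n_frames <- as.integer(floor((L + H) / s) + 1)
  empty <- function() {
    list(scene = gt_scene(frame_size = cfg$frame_size, n_frames = n_frames),
         detections = detections(), fruits = data.frame(),
         embeddings = matrix(numeric(0), 0, 0), config = cfg)
  }
  if (cfg$n_fruits == 0L) return(empty())
  with_seed(cfg$seed, {
    n <- cfg$n_fruits
    size <- runif(n, cfg$fruit_size_range[1L], cfg$fruit_size_range[2L])
    h <- size
    w <- pmin(size * runif(n, 0.9, 1.1), W)
    x <- runif(n, 0, W - w)
    y_world <- runif(n, 0, L)
    emb <- unit_rows(matrix(rnorm(n * 128L), n))
    fruits <- data.frame(id = seq_len(n), x = x, y_world = y_world,
                         w = w, h = h)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      # image top edge of fruit i at frame t: y_world - L + t*s
      offs <- y_world[i] - L
      t0 <- max(0L, as.integer(floor((-h[i] - offs) / s)) )
      t1 <- min(n_frames - 1L, as.integer(ceiling((H - offs) / s)))
      if (t1 < t0) next
      t <- t0:t1
      iy <- offs + t * s
      vis <- iy + h[i] > 0 & iy < H
      t <- t[vis]; iy <- iy[vis]
      if (!length(t)) next
      rows[[i]] <- data.frame(id = i, frame = t, x = x[i], y = iy,
                              w = w[i], h = h[i])
    }
    boxes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    scene <- gt_scene(boxes, frame_size = cfg$frame_size,
                      n_frames = n_frames)
    b <- scene$boxes
    dets <- detections(frame = b$frame, x = b$x, y = b$y, w = b$w, h = b$h,
                       conf = rep(1, nrow(b)),
                       embedding = lapply(b$id, function(i) emb[i, ]),
                       source_id = b$id)
    list(scene = scene, detections = dets, fruits = fruits,
         embeddings = emb, config = cfg)
  })
}

#' Corrupt an ideal detection stream
#'
#' Applies, in order: occlusion episodes (contiguous per-fruit dropouts),
#' independent per-fruit-frame flicker dropouts, Gaussian jitter on box
#' centers and log-sizes, resampled confidences, embedding noise
#' (renormalized to unit length), and Poisson false positives per frame
#' with fresh random embeddings. Each phase draws from its own derived RNG
#' substream, so occlusions are identical across runs that vary only
#' `p_miss`.
#'
#' @param sim output of [generate_scene()] (or an ideal [detections] stream
#'   plus `scene`).
#' @param ccfg a [corruption_config].
#' @return A [detections] stream (with `source_id` provenance, `NA` for
#'   false positives).
#' @export
corrupt_detections <- function(sim, ccfg = corruption_config()) {
  ideal <- sim$detections
  scene <- sim$scene
  scfg <- sim$config
  W <- scene$frame_size[1L]; H <- scene$frame_size[2L]
  n <- nrow(ideal)
  seeds <- derive_seeds(ccfg$seed, 5L)
  dim_e <- ccfg$embedding_dim
  base_emb <- sim$embeddings
  if (ncol(base_emb) && ncol(base_emb) != dim_e) {
    # embed/truncate the base vectors into the requested dimension
    if (ncol(base_emb) > dim_e) {
      base_emb <- unit_rows(base_emb[, seq_len(dim_e), drop = FALSE])
    } else {
      base_emb <- cbind(base_emb,
                        matrix(0, nrow(base_emb), dim_e - ncol(base_emb)))
    }
  }

  # phase 1: occlusion episodes, one substream
  occluded <- rep(FALSE, n)
  with_seed(seeds[1L], {
    for (fid in sort(unique(ideal$source_id))) {
      idx <- which(ideal$source_id == fid)
      frames <- ideal$frame[idx]
      n_ep <- rpois(1L, ccfg$occlusion_rate)
      if (n_ep == 0L) next
      for (e in seq_len(n_ep)) {
        start <- runif(1L, min(frames), max(frames))
        dur <- runif(1L, ccfg$occlusion_duration[1L],
                     ccfg$occlusion_duration[2L])
        occluded[idx[frames >= start & frames < start + dur]] <- TRUE
      }
    }
  })

  # phase 2: flicker — one uniform per fruit-frame, thresholded at p_miss
  flicker <- with_seed(seeds[2L], runif(n) < ccfg$p_miss)

  # phase 3: jitter / confidence / embedding noise drawn for every ideal
  # detection (kept or not) so survivors' values do not depend on p_miss
  pert <- with_seed(seeds[3L], {
    list(dcx = rnorm(n, 0, ccfg$jitter_sigma),
         dcy = rnorm(n, 0, ccfg$jitter_sigma),
         # relative log-size jitter, capped so sub-pixel clipped slivers
         # cannot blow up exp(log-size + noise)
         dlw = rnorm(n, 0, pmin(ccfg$jitter_sigma / pmax(ideal$w, 1), 0.5)),
         dlh = rnorm(n, 0, pmin(ccfg$jitter_sigma / pmax(ideal$h, 1), 0.5)),
         conf = rnorm(n, ccfg$confidence_model$true[1L],
                      ccfg$confidence_model$true[2L]),
         enoise = matrix(rnorm(n * dim_e, 0,
                               ccfg$embedding_noise / sqrt(dim_e)), n))
  })

  keep <- !occluded & !flicker
  out <- NULL
  if (any(keep)) {
    cx <- ideal$x[keep] + ideal$w[keep] / 2 + pert$dcx[keep]
    cy <- ideal$y[keep] + ideal$h[keep] / 2 + pert$dcy[keep]
    w <- pmax(exp(log(ideal$w[keep]) + pert$dlw[keep]), 1)
    h <- pmax(exp(log(ideal$h[keep]) + pert$dlh[keep]), 1)
    conf <- pmin(pmax(pert$conf[keep], 0), 1)
    E <- base_emb[ideal$source_id[keep], , drop = FALSE] +
      pert$enoise[keep, , drop = FALSE]
    E <- unit_rows(E)
    out <- data.frame(frame = ideal$frame[keep], x = cx - w / 2, y = cy - h / 2,
                      w = w, h = h, conf = conf,
                      source_id = ideal$source_id[keep])
    out$embedding <- I(lapply(seq_len(nrow(out)), function(i) E[i, ]))
  }

  # phase 4: false positives
  fp <- with_seed(seeds[4L], {
    counts <- rpois(scene$n_frames, ccfg$fp_rate)
    total <- sum(counts)
    if (total == 0L) NULL else {
      size_rng <- if (!is.null(scfg)) scfg$fruit_size_range else
        range(c(scene$boxes$w, scene$boxes$h))
      sz <- runif(total, size_rng[1L], size_rng[2L])
      wf <- pmin(sz, W); hf <- pmin(sz, H)
      d <- data.frame(frame = rep(seq_len(scene$n_frames) - 1L, counts),
                      x = runif(total, 0, W - wf),
                      y = runif(total, 0, H - hf), w = wf, h = hf,
                      conf = pmin(pmax(rnorm(total,
                                             ccfg$confidence_model$false[1L],
                                             ccfg$confidence_model$false[2L]),
                                       0), 1),
                      source_id = NA_integer_)
      Ef <- unit_rows(matrix(rnorm(total * dim_e), total))
      d$embedding <- I(lapply(seq_len(total), function(i) Ef[i, ]))
      d
    }
  })

  pieces <- Filter(Negate(is.null), list(out, fp))
  if (!length(pieces)) return(detections())
  as_detections(do.call(rbind, pieces))
}

#' Write a simulated pass to disk
#'
#' Emits a MOT `det.txt`/`gt.txt` pair, an embeddings sidecar CSV and a YAML
#' scene manifest into `dir`.
#'
#' @param sim output of [generate_scene()].
#' @param dets the (possibly corrupted) detection stream to write.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(sim, dets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_detections(dets, file.path(dir, "det.txt"))
  write_ground_truth(sim$scene, file.path(dir, "gt.txt"))
  if (!is.null(dets$embedding))
    write_embeddings(dets, file.path(dir, "embeddings.csv"))
  manifest <- list(frame_size = as.numeric(sim$scene$frame_size),
                   n_frames = sim$scene$n_frames,
                   n_fruits = nrow(sim$fruits),
                   config = unclass(sim$config))
  yaml::write_yaml(manifest, file.path(dir, "scene.yaml"))
  invisible(dir)
}
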