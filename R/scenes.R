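#' Configuration of the synthetic feeding-station scene generator
#'
#' The generator emulates baited camera-trap stills: a static background
#' with a sky gradient and slow cloud structure, a bright reflective
#' feeding table, dark seed containers sitting on it, and dark bird
#' silhouettes of variable size and orientation placed on the table. The
#' nuisances that plague real footage are modelled explicitly and can be
#' toggled: mirror-like reflections of on-table birds (drawn only inside
#' the table region), offset cast shadows, partial occlusion by a
#' container (the annotation keeps the full bird extent, so occlusion
#' degrades IoU exactly as in real ground truth), per-frame global
#' lighting gain, and dark background clutter that attracts false
#' positives outside the table area. Frame-level class skew is i.i.d.:
#' each frame contains birds with probability `bird_prob` (default 0.11,
#' the skew of the motivating field trial) and positive frames hold 1 to
#' `max_birds` (default 5) birds.
#'
#' @param frame_size `c(width, height)` in pixels.
#' @param table_region [bbox()] of the feeding table within the frame.
#' @param table_albedo Table intensity (bright, reflective aluminum).
#' @param background List: `sky_top`, `sky_bottom` (gradient endpoints),
#'   `cloud_amplitude` and `cloud_n` (smooth intensity blobs),
#'   `grass_amplitude` (fine texture noise below the horizon).
#' @param n_containers Number of seed containers on the table.
#' @param container_size `c(w, h)` of a container in pixels.
#' @param container_intensity Container gray level.
#' @param bird_prob Probability a frame contains any bird.
#' @param max_birds Maximum birds per positive frame.
#' @param bird_scale_range `c(min, max)` sprite scale in pixels (the bird
#'   silhouette spans roughly 2.3x this scale tip to tail).
#' @param bird_intensity `c(min, max)` dark-gray range of the silhouette
#'   (cowbird-dark, high contrast against the table).
#' @param reflection List: `on`, `contrast` (0-1 attenuation of the
#'   mirrored silhouette; 0.5 means halfway between table and bird).
#' @param shadow List: `on`, `offset` (`c(dx, dy)` pixels), `darkness`
#'   (fractional darkening under the shadow mask).
#' @param lighting `c(min, max)` multiplicative per-frame gain.
#' @param occlusion_prob Probability an on-table bird is partially covered
#'   by a container.
#' @param n_distractors Dark cloud-smudge blobs placed in the sky region
#'   per frame (background clutter; 0 disables).
#' @param crop_region [bbox()] used by crop ablations; defaults to the
#'   table region padded by 12 px.
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(frame_size = c(256L, 192L),
                         table_region = bbox(40, 104, 176, 56),
                         table_albedo = 205,
                         background = list(sky_top = 120, sky_bottom = 170,
                                           cloud_amplitude = 22, cloud_n = 3,
                                           grass_amplitude = 10),
                         n_containers = 2L,
                         container_size = c(16L, 12L),
                         container_intensity = 95,
                         bird_prob = 0.11,
                         max_birds = 5L,
                         bird_scale_range = c(10, 16),
                         bird_intensity = c(25, 60),
                         reflection = list(on = TRUE, contrast = 0.5),
                         shadow = list(on = TRUE, offset = c(3L, 3L),
                                       darkness = 0.3),
                         lighting = c(0.75, 1.25),
                         occlusion_prob = 0.15,
                         n_distractors = 2L,
                         crop_region = NULL) {
  cfg <- list(frame_size = as.integer(frame_size),
              table_region = as_box(table_region),
              table_albedo = table_albedo, background = background,
              n_containers = as.integer(n_containers),
              container_size = as.integer(container_size),
              container_intensity = container_intensity,
              bird_prob = bird_prob, max_birds = as.integer(max_birds),
              bird_scale_range = bird_scale_range,
              bird_intensity = bird_intensity,
              reflection = reflection, shadow = shadow,
              lighting = lighting, occlusion_prob = occlusion_prob,
              n_distractors = as.integer(n_distractors))
  cfg$crop_region <- if (is.null(crop_region)) {
    tr <- cfg$table_region
    m <- 12
    bbox(max(0, tr$x - m), max(0, tr$y - m),
         min(cfg$frame_size[1], tr$x + tr$w + m) - max(0, tr$x - m),
         min(cfg$frame_size[2], tr$y + tr$h + m) - max(0, tr$y - m))
  } else {
    as_box(crop_region)
  }
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  w <- cfg$frame_size[1]; h <- cfg$frame_size[2]
  tr <- cfg$table_region
  if (tr$x + tr$w > w || tr$y + tr$h > h) stop("table region outside frame")
  probs <- c(cfg$bird_prob, cfg$occlusion_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$max_birds < 1) stop("max_birds must be >= 1")
  # worst-case rotated silhouette bounding box vs table extent
  worst <- 2.7 * max(cfg$bird_scale_range)
  if (worst > min(tr$w, tr$h)) {
    stop("infeasible geometry: largest bird (", round(worst),
         " px) exceeds the table region")
  }
  invisible(cfg)
}

#' Procedural bird silhouette sprite
#'
#' A parametric dark silhouette — ellipse body, overlapping round head,
#' tapered triangular tail — rotated to an arbitrary orientation and
#' rasterized with its tight bounding box. Procedural sprites keep the
#' ground truth exact: every mask pixel is known. Rotating by 180 degrees
#' yields the point-mirrored mask; the mask pixel count scales with the
#' square of `scale`.
#'
#' @param scale Sprite scale in pixels (body semi-major axis).
#' @param orientation Rotation in degrees, counterclockwise.
#' @param intensity Silhouette gray level.
#' @return A list: `mask` (logical matrix, tight), `patch` (intensity
#'   matrix with `NA` off-mask), `w`, `h` (tight box dimensions).
#' @export
make_bird_sprite <- function(scale, orientation = 0, intensity = 40) {
  s <- scale
  stopifnot(s > 0)
  th <- orientation * pi / 180
  R <- ceiling(1.5 * s) + 1
  coords <- seq(-R, R)
  gx <- matrix(coords, 2 * R + 1, 2 * R + 1, byrow = TRUE)
  gy <- matrix(coords, 2 * R + 1, 2 * R + 1)
  # rotate into the sprite's object frame
  u <- cos(th) * gx + sin(th) * gy
  v <- -sin(th) * gx + cos(th) * gy
  body <- (u / (0.95 * s))^2 + (v / (0.72 * s))^2 <= 1
  head <- (u - 0.72 * s)^2 + (v + 0.20 * s)^2 <= (0.45 * s)^2
  tail_u <- u >= -1.15 * s & u <= -0.55 * s
  tail_hw <- 0.02 * s + 0.28 * s * (u + 1.15 * s) / (0.60 * s)
  tail <- tail_u & abs(v) <= tail_hw
  mask <- body | head | tail
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  mask <- mask[rows[1]:rows[length(rows)], cols[1]:cols[length(cols)],
               drop = FALSE]
  patch <- matrix(NA_real_, nrow(mask), ncol(mask))
  patch[mask] <- intensity
  list(mask = mask, patch = patch, w = ncol(mask), h = nrow(mask))
}

#' Render one synthetic scene with ground truth
#'
#' Draws the background, table and containers; with probability
#' `bird_prob` places `k ~ Uniform{1..max_birds}` birds on the table,
#' each with optional reflection (vertically mirrored below the bird,
#' clipped to the table region, contrast-attenuated), offset cast shadow,
#' and possible partial occlusion by a container drawn over the bird's
#' lower half (the annotation keeps the full extent and sets the
#' `occluded` flag). Finally the whole frame is multiplied by a sampled
#' lighting gain. The same seed reproduces the frame bit for bit.
#'
#' @param cfg A [scene_config()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG
#'   stream (used by [generate_dataset()] for a single sequential stream).
#' @param frame_id Identifier copied into the annotation rows.
#' @return List with `image` (intensity matrix, \[0, 255\]) and
#'   `annotation` (data frame: `frame_id`, `x`, `y`, `w`, `h`, `label`,
#'   `occluded`, `on_table`; zero rows for bird-free frames).
#' @export
render_scene <- function(cfg, seed = NULL, frame_id = "frame_1") {
  validate_scene_config(cfg)
  with_seed(seed, render_scene_impl(cfg, frame_id))
}

render_scene_impl <- function(cfg, frame_id) {
  w <- cfg$frame_size[1]; h <- cfg$frame_size[2]
  tr <- cfg$table_region
  bg <- cfg$background
  # sky gradient
  img <- matrix(rep(seq(bg$sky_top, bg$sky_bottom, length.out = h), w), h, w)
  # smooth cloud blobs in the sky area
  if (bg$cloud_n > 0 && bg$cloud_amplitude > 0) {
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    for (i in seq_len(bg$cloud_n)) {
      cx <- runif(1, 1, w); cy <- runif(1, 1, max(2, tr$y - 5))
      sg <- runif(1, 12, 35)
      amp <- runif(1, -1, 1) * bg$cloud_amplitude
      img <- img + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sg^2))
    }
  }
  # fine grass texture below the horizon (table top edge)
  if (bg$grass_amplitude > 0 && tr$y < h) {
    n_below <- h - tr$y
    img[(tr$y + 1):h, ] <- img[(tr$y + 1):h, ] +
      matrix(runif(n_below * w, -bg$grass_amplitude, bg$grass_amplitude),
             n_below, w)
  }
  # the bright table
  trr <- tr$y + seq_len(tr$h); trc <- tr$x + seq_len(tr$w)
  img[trr, trc] <- cfg$table_albedo +
    matrix(runif(tr$h * tr$w, -4, 4), tr$h, tr$w)
  # dark cloud-smudge distractors in the sky (background clutter)
  if (cfg$n_distractors > 0 && tr$y > 20) {
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    for (i in seq_len(cfg$n_distractors)) {
      cx <- runif(1, 15, w - 15)
      cy <- runif(1, 10, tr$y - 12)
      a <- runif(1, 6, 12); b <- runif(1, 4, 9)
      dark <- runif(1, cfg$bird_intensity[1], cfg$bird_intensity[2] + 20)
      inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
      img[inside] <- dark + runif(sum(inside), -5, 5)
    }
  }
  # containers on the table
  draw_container <- function(img, cx0, cy0) {
    cw <- cfg$container_size[1]; ch <- cfg$container_size[2]
    rr <- cy0 + seq_len(ch); cc <- cx0 + seq_len(cw)
    img[rr, cc] <- cfg$container_intensity +
      matrix(runif(ch * cw, -3, 3), ch, cw)
    img
  }
  containers <- list()
  for (i in seq_len(cfg$n_containers)) {
    cw <- cfg$container_size[1]; ch <- cfg$container_size[2]
    cx0 <- tr$x + sample.int(tr$w - cw, 1) - 1L
    cy0 <- tr$y + sample.int(tr$h - ch, 1) - 1L
    img <- draw_container(img, cx0, cy0)
    containers[[i]] <- c(cx0, cy0)
  }
  # birds
  ann <- data.frame(frame_id = character(0), x = integer(0), y = integer(0),
                    w = integer(0), h = integer(0), label = character(0),
                    occluded = logical(0), on_table = logical(0))
  if (runif(1) < cfg$bird_prob) {
    k <- sample.int(cfg$max_birds, 1)
    for (b in seq_len(k)) {
      sc <- runif(1, cfg$bird_scale_range[1], cfg$bird_scale_range[2])
      ori <- runif(1, 0, 360)
      inten <- runif(1, cfg$bird_intensity[1], cfg$bird_intensity[2])
      sp <- make_bird_sprite(sc, ori, inten)
      # place so the tight box sits inside the table region
      if (sp$w >= tr$w || sp$h >= tr$h) next
      bx <- tr$x + sample.int(tr$w - sp$w, 1) - 1L
      by <- tr$y + sample.int(tr$h - sp$h, 1) - 1L
      rr <- by + seq_len(sp$h); cc <- bx + seq_len(sp$w)
      # cast shadow first (under the bird, offset)
      if (isTRUE(cfg$shadow$on)) {
        srr <- rr + cfg$shadow$offset[2]; scc <- cc + cfg$shadow$offset[1]
        ok <- srr >= 1 & srr <= h
        okc <- scc >= 1 & scc <= w
        sm <- sp$mask[ok, okc, drop = FALSE]
        sub <- img[srr[ok], scc[okc], drop = FALSE]
        sub[sm] <- sub[sm] * (1 - cfg$shadow$darkness)
        img[srr[ok], scc[okc]] <- sub
      }
      # the bird itself, with mild per-pixel texture
      sub <- img[rr, cc, drop = FALSE]
      nm <- sum(sp$mask)
      sub[sp$mask] <- inten + runif(nm, -4, 4)
      img[rr, cc] <- sub
      # mirror reflection below, only inside the table region
      if (isTRUE(cfg$reflection$on)) {
        rmask <- sp$mask[rev(seq_len(sp$h)), , drop = FALSE]
        ry <- by + sp$h   # starts right under the bird
        rrr <- ry + seq_len(sp$h)
        ok <- rrr >= (tr$y + 1) & rrr <= (tr$y + tr$h)
        if (any(ok)) {
          rm <- rmask[ok, , drop = FALSE]
          sub <- img[rrr[ok], cc, drop = FALSE]
          cr <- cfg$reflection$contrast
          sub[rm] <- (1 - cr) * sub[rm] + cr * inten
          img[rrr[ok], cc] <- sub
        }
      }
      occluded <- FALSE
      if (runif(1) < cfg$occlusion_prob) {
        # container drawn over the bird's lower portion
        cw <- cfg$container_size[1]; ch <- cfg$container_size[2]
        ox0 <- max(0L, min(w - cw, bx + sp$w %/% 2 - cw %/% 2))
        oy0 <- max(0L, min(h - ch, by + sp$h - ch %/% 2))
        img <- draw_container(img, ox0, oy0)
        occluded <- TRUE
      }
      ann <- rbind(ann, data.frame(frame_id = frame_id, x = bx, y = by,
                                   w = sp$w, h = sp$h, label = "bird",
                                   occluded = occluded, on_table = TRUE))
    }
  }
  gain <- runif(1, cfg$lighting[1], cfg$lighting[2])
  img <- pmin(pmax(img * gain, 0), 255)
  list(image = img, annotation = ann)
}

#' Generate a synthetic dataset on disk
#'
#' Renders `n_frames` scenes from a single sequential RNG stream seeded
#' once, writes each as a zero-padded PNG, a single `annotations.csv`,
#' and a `manifest.json` capturing the full configuration and seed —
#' regenerating from the manifest reproduces every file bit for bit.
#'
#' @param n_frames Number of frames (>= 1).
#' @param cfg A [scene_config()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `frames` (PNG paths),
#'   `annotations` (the data frame) and `manifest` (path).
#' @export
generate_dataset <- function(n_frames, cfg = scene_config(), seed = 1L,
                             dir) {
  stopifnot(n_frames >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  digits <- max(6, nchar(as.character(n_frames)))
  res <- with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      fid <- sprintf(paste0("frame_%0", digits, "d"), i)
      sc <- render_scene_impl(cfg, fid)
      path <- file.path(dir, paste0(fid, ".png"))
      write_frame(sc$image, path)
      list(path = path, annotation = sc$annotation)
    })
  })
  ann <- do.call(rbind, lapply(res, `[[`, "annotation"))
  ann_path <- file.path(dir, "annotations.csv")
  utils::write.csv(ann, ann_path, row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(schema = "birdcascade/dataset",
                            schema_version = 1L, n_frames = n_frames,
                            seed = seed, config = scene_config_to_list(cfg)),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, frames = vapply(res, `[[`, character(1), "path"),
                 annotations = ann, manifest = manifest))
}

scene_config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$table_region <- unclass(out$table_region)
  out$crop_region <- unclass(out$crop_region)
  out
}

#' Rebuild a scene config from a dataset manifest
#'
#' @param manifest Path to a `manifest.json` written by
#'   [generate_dataset()].
#' @return A list with `cfg`, `seed`, `n_frames`.
#' @export
read_manifest <- function(manifest) {
  p <- jsonlite::fromJSON(manifest, simplifyVector = TRUE)
  cl <- p$config
  cfg <- scene_config(frame_size = cl$frame_size,
                      table_region = as_box(as.list(cl$table_region)),
                      table_albedo = cl$table_albedo,
                      background = as.list(cl$background),
                      n_containers = cl$n_containers,
                      container_size = cl$container_size,
                      container_intensity = cl$container_intensity,
                      bird_prob = cl$bird_prob, max_birds = cl$max_birds,
                      bird_scale_range = cl$bird_scale_range,
                      bird_intensity = cl$bird_intensity,
                      reflection = as.list(cl$reflection),
                      shadow = as.list(cl$shadow),
                      lighting = cl$lighting,
                      occlusion_prob = cl$occlusion_prob,
                      n_distractors = cl$n_distractors,
                      crop_region = as_box(as.list(cl$crop_region)))
  list(cfg = cfg, seed = p$seed, n_frames = p$n_frames)
}

#' Build an in-memory training set from the generator
#'
#' Positive windows are square context crops of annotated birds taken
#' from scenes rendered with birds forced present: the tight box is
#' expanded to a square of side `max(w, h)` centered on the bird (shifted
#' to stay inside the frame), so the window margin is real scene
#' background, exactly what a detection window of the matching scale
#' sees. Negatives are whole bird-free frames. Both inherit every
#' nuisance enabled in `cfg`, so the detector trains under the same
#' conditions it is evaluated on.
#'
#' @param cfg A [scene_config()].
#' @param n_pos Number of positive crops.
#' @param n_neg_frames Number of bird-free frames.
#' @param seed Integer seed.
#' @return List with `positives` (crop matrices), `negatives` (frame
#'   matrices) and `pos_meta` (data frame of crop geometry).
#' @export
make_training_set <- function(cfg, n_pos = 200L, n_neg_frames = 20L,
                              seed = 1L) {
  pos_cfg <- cfg; pos_cfg$bird_prob <- 1
  neg_cfg <- cfg; neg_cfg$bird_prob <- 0
  with_seed(seed, {
    positives <- list()
    meta <- list()
    while (length(positives) < n_pos) {
      sc <- render_scene_impl(pos_cfg, "train")
      a <- sc$annotation
      for (i in seq_len(nrow(a))) {
        if (length(positives) >= n_pos) break
        # square context crop centered on the bird box
        side <- max(a$w[i], a$h[i])
        fw <- ncol(sc$image); fh <- nrow(sc$image)
        cx <- a$x[i] + a$w[i] / 2; cy <- a$y[i] + a$h[i] / 2
        x0 <- min(max(0, round(cx - side / 2)), fw - side)
        y0 <- min(max(0, round(cy - side / 2)), fh - side)
        crop <- sc$image[y0 + seq_len(side), x0 + seq_len(side),
                         drop = FALSE]
        positives[[length(positives) + 1]] <- crop
        meta[[length(meta) + 1]] <- a[i, c("w", "h", "occluded")]
      }
    }
    negatives <- lapply(seq_len(n_neg_frames), function(i) {
      render_scene_impl(neg_cfg, "neg")$image
    })
    list(positives = positives, negatives = negatives,
         pos_meta = do.call(rbind, meta))
  })
}
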