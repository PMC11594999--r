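#' Default parameters of the synthetic FLIM cell generator
#'
#' The generator emulates three red-blood-cell phenotypes observed in
#' label-free FLIM of sickle cell disease (SCD) blood films:
#' \describe{
#'   \item{control}{round cell, homogeneous cytoplasm, no bright foci;}
#'   \item{nonsickled}{round SCD cell carrying 0-3 small high-lifetime dots;}
#'   \item{sickled}{elongated cell with an irregular membrane-adherent
#'     high-lifetime patch (plus possible dots) and a wider lifetime
#'     distribution.}
#' }
#' Class means and pixel SDs (picoseconds) default to the per-cell values
#' reported for the three phenotypes: means 175.531 / 193.891 / 253.335 ps
#' and SDs 30.222 / 28.091 / 58.614 ps. The configured mean and SD refer to
#' the whole ROI \emph{including} planted structures: the generator
#' calibrates the base cytoplasm level and noise scale of each cell against
#' its planted dot/patch field, so cohort averages recover the configured
#' values by construction.
#'
#' @param cell_diameter_px Cell diameter in pixels (round classes).
#' @param background_lifetime_ps Plasma background lifetime (must exceed the
#'   largest class mean, as plasma shows longer lifetimes than hemoglobin).
#' @param class_means_ps,class_sds_ps Named numeric vectors (control,
#'   nonsickled, sickled): target ROI mean and pixel SD per class.
#' @param cell_mean_jitter_ps SD of the between-cell jitter added to the
#'   class mean (biological cell-to-cell variation).
#' @param texture_fine_sigma_px,texture_coarse_sigma_px Gaussian sigmas
#'   (pixels) of the two spatially correlated components of the cytoplasm
#'   noise field. The field is a variance-preserving mixture of white noise
#'   plus these two smoothed components; spatial correlation of the
#'   lifetime texture is what the LBP features respond to.
#' @param texture_fine_frac,texture_coarse_frac Named vectors (per class):
#'   variance fractions of the fine and coarse correlated components.
#'   Together with the impulse density these carry the texture class
#'   contrast.
#' @param texture_impulse_frac Named vector (per class): fraction of
#'   cytoplasm pixels carrying a positive sub-resolution impulse (bright
#'   single-pixel speckle, emulating incipient high-lifetime nuclei below
#'   the dot scale).
#' @param texture_impulse_amp Impulse amplitude in units of the cytoplasm
#'   noise SD.
#' @param texture_cell_sd,texture_patient_sd SD of the Gaussian jitter
#'   applied to both variance fractions per cell and per patient
#'   (cell-to-cell and subject-to-subject texture variability).
#' @param impulse_cell_sd,impulse_patient_sd SD of the jitter applied to
#'   the impulse fraction per cell and per patient.
#' @param dot_count_range Integer pair: dots per SCD cell drawn uniformly
#'   from this range (never in controls).
#' @param dot_radius_px Dot disc radius in pixels.
#' @param dot_lifetime_offset_ps Lifetime elevation of dot pixels.
#' @param patch_area_fraction Range: fraction of the cell footprint covered
#'   by the sickled cell's polymerization patch.
#' @param patch_lifetime_offset_ps Range: lifetime elevation of the patch,
#'   drawn uniformly per cell.
#' @param pixel_noise_model \code{"gaussian"} (default) or
#'   \code{"shot-like"} (noise SD scaling with the square root of the local
#'   mean lifetime).
#' @return Validated list of class \code{"flim_gen_params"}.
#' @export
flim_default_params <- function(cell_diameter_px = 60L,
                                background_lifetime_ps = 450,
                                class_means_ps = c(control = 175.531,
                                                   nonsickled = 193.891,
                                                   sickled = 253.335),
                                class_sds_ps = c(control = 30.222,
                                                 nonsickled = 28.091,
                                                 sickled = 58.614),
                                cell_mean_jitter_ps = 8,
                                texture_fine_sigma_px = 0.8,
                                texture_coarse_sigma_px = 1.8,
                                texture_fine_frac = c(control = 0.15,
                                                      nonsickled = 0.15,
                                                      sickled = 0.40),
                                texture_coarse_frac = c(control = 0.05,
                                                        nonsickled = 0.12,
                                                        sickled = 0.20),
                                texture_impulse_frac = c(control = 0.005,
                                                         nonsickled = 0.012,
                                                         sickled = 0.030),
                                texture_impulse_amp = 3,
                                texture_cell_sd = 0.05,
                                texture_patient_sd = 0.04,
                                impulse_cell_sd = 0.004,
                                impulse_patient_sd = 0.003,
                                dot_count_range = c(0L, 3L),
                                dot_radius_px = 2,
                                dot_lifetime_offset_ps = 150,
                                patch_area_fraction = c(0.10, 0.30),
                                patch_lifetime_offset_ps = c(80, 200),
                                pixel_noise_model = c("gaussian", "shot-like")) {
  p <- list(cell_diameter_px = as.integer(cell_diameter_px),
            background_lifetime_ps = background_lifetime_ps,
            class_means_ps = class_means_ps,
            class_sds_ps = class_sds_ps,
            cell_mean_jitter_ps = cell_mean_jitter_ps,
            texture_fine_sigma_px = texture_fine_sigma_px,
            texture_coarse_sigma_px = texture_coarse_sigma_px,
            texture_fine_frac = texture_fine_frac,
            texture_coarse_frac = texture_coarse_frac,
            texture_impulse_frac = texture_impulse_frac,
            texture_impulse_amp = texture_impulse_amp,
            texture_cell_sd = texture_cell_sd,
            texture_patient_sd = texture_patient_sd,
            impulse_cell_sd = impulse_cell_sd,
            impulse_patient_sd = impulse_patient_sd,
            dot_count_range = as.integer(dot_count_range),
            dot_radius_px = dot_radius_px,
            dot_lifetime_offset_ps = dot_lifetime_offset_ps,
            patch_area_fraction = patch_area_fraction,
            patch_lifetime_offset_ps = patch_lifetime_offset_ps,
            pixel_noise_model = match.arg(pixel_noise_model))
  class(p) <- "flim_gen_params"
  validate_gen_params(p)
  p
}

cell_classes <- c("control", "nonsickled", "sickled")

#' Validate generator parameters
#'
#' @param p A \code{"flim_gen_params"} list.
#' @return \code{p} invisibly; errors on violation.
#' @export
validate_gen_params <- function(p) {
  stopifnot(inherits(p, "flim_gen_params"))
  if (p$cell_diameter_px < 12L)
    stop("cell_diameter_px too small to host an ROI")
  need <- function(v, nm) {
    if (!all(cell_classes %in% names(v)))
      stop(nm, " must be named for classes: ", paste(cell_classes, collapse = ", "))
  }
  need(p$class_means_ps, "class_means_ps"); need(p$class_sds_ps, "class_sds_ps")
  need(p$texture_fine_frac, "texture_fine_frac")
  need(p$texture_coarse_frac, "texture_coarse_frac")
  need(p$texture_impulse_frac, "texture_impulse_frac")
  if (any(p$texture_impulse_frac < 0) || any(p$texture_impulse_frac > 0.2))
    stop("texture_impulse_frac must lie in [0, 0.2]")
  if (p$impulse_cell_sd < 0 || p$impulse_patient_sd < 0)
    stop("impulse jitter SDs must be nonnegative")
  fr <- c(p$texture_fine_frac, p$texture_coarse_frac)
  if (any(fr < 0) || any(p$texture_fine_frac + p$texture_coarse_frac > 0.95))
    stop("texture variance fractions must be nonnegative with fine + coarse <= 0.95")
  if (p$texture_fine_sigma_px <= 0 || p$texture_coarse_sigma_px <= 0)
    stop("texture sigmas must be positive")
  if (p$texture_cell_sd < 0 || p$texture_patient_sd < 0)
    stop("texture jitter SDs must be nonnegative")
  pos <- c(p$background_lifetime_ps, p$class_means_ps, p$class_sds_ps,
           p$dot_radius_px, p$dot_lifetime_offset_ps, p$patch_lifetime_offset_ps)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all lifetime parameters must be strictly positive")
  if (p$background_lifetime_ps <= max(p$class_means_ps))
    stop("background (plasma) lifetime must exceed every cytoplasm class mean")
  if (length(p$dot_count_range) != 2L || any(p$dot_count_range < 0L) ||
      p$dot_count_range[1L] > p$dot_count_range[2L])
    stop("dot_count_range must be a nondecreasing nonnegative integer pair")
  if (length(p$patch_area_fraction) != 2L || any(p$patch_area_fraction <= 0) ||
      any(p$patch_area_fraction >= 1) ||
      p$patch_area_fraction[1L] > p$patch_area_fraction[2L])
    stop("patch_area_fraction must be an increasing pair inside (0, 1)")
  if (p$cell_mean_jitter_ps < 0)
    stop("cell_mean_jitter_ps must be nonnegative")
  invisible(p)
}

# deterministic 32-bit substream seed: one independent-ish seed per cell,
# derived from the master seed and a counter (all arithmetic exact in doubles)
substream_seed <- function(seed, index) {
  h <- (as.double(seed) %% 2147483647) * 69069 + as.double(index) * 12577 + 1
  as.integer(h %% 2147483647)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# unit-variance correlated noise field: white gaussian convolved with a
# gaussian kernel, renormalized so the pointwise SD stays 1
correlated_noise <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sigma <= 0) return(z)
  k <- gaussian_kernel(sigma)
  EBImage::filter2(z, k, boundary = "circular") / sqrt(sum(k^2))
}

# texture field: variance-preserving mixture of white noise and two
# correlated components (fractions a fine, b coarse), plus sparse positive
# impulses at density q and amplitude amp (in noise-SD units)
texture_field <- function(h, w, a, b, q, amp, sigma_fine, sigma_coarse) {
  a <- min(max(a, 0), 0.95); b <- min(max(b, 0), 0.95 - a)
  z <- sqrt(1 - a - b) * matrix(stats::rnorm(h * w), h, w)
  if (a > 0) z <- z + sqrt(a) * correlated_noise(h, w, sigma_fine)
  if (b > 0) z <- z + sqrt(b) * correlated_noise(h, w, sigma_coarse)
  q <- min(max(q, 0), 0.2)
  if (q > 0) {
    k <- round(q * h * w)
    if (k > 0) {
      idx <- sample.int(h * w, k)
      z[idx] <- z[idx] + amp
      # restandardize so the field keeps zero mean and unit variance
      qe <- k / (h * w)
      z <- (z - qe * amp) / sqrt(1 + qe * (1 - qe) * amp^2)
    }
  }
  z
}

# randomized blob grown from a seed pixel across allowed pixels (8-neighborhood)
grow_blob <- function(allowed, seed_idx, target_px) {
  h <- nrow(allowed); w <- ncol(allowed)
  in_blob <- matrix(FALSE, h, w)
  frontier <- seed_idx
  taken <- 0L
  nbr <- cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  while (taken < target_px && length(frontier) > 0L) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    frontier <- frontier[frontier != pick]
    r <- (pick - 1L) %% h + 1L; cc <- (pick - 1L) %/% h + 1L
    if (in_blob[pick]) next
    in_blob[pick] <- TRUE; taken <- taken + 1L
    rr <- r + nbr[, 1L]; ccn <- cc + nbr[, 2L]
    ok <- rr >= 1L & rr <= h & ccn >= 1L & ccn <= w
    idx <- (ccn[ok] - 1L) * h + rr[ok]
    idx <- idx[allowed[idx] & !in_blob[idx]]
    frontier <- c(frontier, idx)
  }
  in_blob
}

#' Generate one synthetic single-cell FLIM matrix
#'
#' Draws a cell of the requested phenotype on a plasma background and
#' returns the lifetime matrix together with its cell record (ROI rectangle
#' strictly inside the cell footprint) and a ground-truth log of planted
#' structures. Control and non-sickled cells are discs; sickled cells are
#' elongated ellipses (axis ratio 3.2). Dots are discs of elevated lifetime
#' placed inside the ROI of SCD cells; the sickled patch is an irregular
#' blob grown from a random boundary pixel of the footprint, so it always
#' touches the cell boundary.
#'
#' @param cell_class \code{"control"}, \code{"nonsickled"} or
#'   \code{"sickled"}.
#' @param params [flim_default_params()] list.
#' @param seed Integer seed; every cell is fully reproducible from it.
#' @param texture_shift Length-2 numeric: additive shift of the (fine,
#'   coarse) texture variance fractions, used by [generate_cohort()] to
#'   model patient-level texture variability.
#' @return List with \code{matrix} (lifetimes, ps), \code{record} (one-row
#'   data frame in manifest schema), \code{roi} ([roi_rect()]) and
#'   \code{log} (list: dot centers/radius/offset, patch size/offset,
#'   realized base level and noise SD).
#' @export
generate_cell <- function(cell_class, params = flim_default_params(), seed = 1L,
                          texture_shift = c(0, 0, 0)) {
  if (!cell_class %in% cell_classes)
    stop("unknown cell class: ", cell_class,
         " (expected one of ", paste(cell_classes, collapse = ", "), ")")
  validate_gen_params(params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  d <- params$cell_diameter_px
  if (cell_class == "sickled") {
    a <- 0.80 * d            # semi-major axis
    b <- a / 3.2             # semi-minor: elongated footprint
    half <- ceiling(a * 1.15)
  } else {
    a <- b <- d / 2
    half <- ceiling(a * 1.25)
  }
  n <- 2L * half + 1L
  cx <- half; cy <- half                      # 0-based center
  xs <- matrix(rep(0:(n - 1L), each = n), n, n)   # x = column index
  ys <- matrix(rep(0:(n - 1L), times = n), n, n)  # y = row index
  foot <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1

  # inscribed axis-aligned ROI (strictly inside the footprint)
  hx <- floor(a / sqrt(2) * 0.9); hy <- floor(b / sqrt(2) * 0.9)
  roi <- roi_rect(cx - hx, cy - hy, cx + hx + 1L, cy + hy + 1L)

  # --- planted structure field (lifetime offsets, ps) ---
  delta <- matrix(0, n, n)
  log <- list(class = cell_class, dots = NULL, patch_px = 0L,
              patch_offset_ps = NA_real_)

  pick_one <- function(v) v[sample.int(length(v), 1L)]
  if (cell_class != "control") {
    ndots <- pick_one(params$dot_count_range[1L]:params$dot_count_range[2L])
    if (ndots > 0L) {
      rad <- params$dot_radius_px
      margin <- ceiling(rad) + 1L
      centers <- matrix(numeric(0), 0L, 2L)
      tries <- 0L
      while (nrow(centers) < ndots && tries < 200L) {
        tries <- tries + 1L
        px <- pick_one(seq(roi$x0 + margin, roi$x1 - 1L - margin))
        py <- pick_one(seq(roi$y0 + margin, roi$y1 - 1L - margin))
        if (nrow(centers) == 0L ||
            all((centers[, 1L] - px)^2 + (centers[, 2L] - py)^2 >
                (2 * rad + 3)^2))
          centers <- rbind(centers, c(px, py))
      }
      for (k in seq_len(nrow(centers)))
        delta[(xs - centers[k, 1L])^2 + (ys - centers[k, 2L])^2 <= rad^2] <-
          delta[(xs - centers[k, 1L])^2 + (ys - centers[k, 2L])^2 <= rad^2] +
          params$dot_lifetime_offset_ps
      log$dots <- data.frame(x = centers[, 1L], y = centers[, 2L],
                             radius_px = params$dot_radius_px,
                             offset_ps = params$dot_lifetime_offset_ps)
    }
  }

  if (cell_class == "sickled") {
    frac <- stats::runif(1L, params$patch_area_fraction[1L],
                         params$patch_area_fraction[2L])
    u <- stats::runif(1L, params$patch_lifetime_offset_ps[1L],
                      params$patch_lifetime_offset_ps[2L])
    # boundary pixels of the footprint: in footprint, with a 4-neighbor outside
    inner <- foot
    inner[-1, ] <- inner[-1, ] & foot[-n, ]; inner[-n, ] <- inner[-n, ] & foot[-1, ]
    inner[, -1] <- inner[, -1] & foot[, -n]; inner[, -n] <- inner[, -n] & foot[, -1]
    boundary <- which(foot & !inner)
    blob <- grow_blob(foot, boundary[sample.int(length(boundary), 1L)],
                      round(frac * sum(foot)))
    delta[blob] <- delta[blob] + u
    log$patch_px <- sum(blob); log$patch_offset_ps <- u
  }

  # --- calibration: configured class mean/SD refer to the whole ROI ---
  target_mean <- params$class_means_ps[[cell_class]]
  target_sd <- params$class_sds_ps[[cell_class]]
  droi <- delta[(roi$y0 + 1L):roi$y1, (roi$x0 + 1L):roi$x1]
  vd <- mean((droi - mean(droi))^2)
  cap <- (0.8 * target_sd)^2
  if (vd > cap) {            # structures alone exceed the SD budget: shrink them
    scl <- sqrt(cap / vd)
    delta <- delta * scl
    droi <- droi * scl
    vd <- cap
    if (!is.null(log$dots)) log$dots$offset_ps <- log$dots$offset_ps * scl
    if (!is.na(log$patch_offset_ps)) log$patch_offset_ps <- log$patch_offset_ps * scl
  }
  noise_sd <- sqrt(target_sd^2 - vd)
  jitter <- stats::rnorm(1L, 0, params$cell_mean_jitter_ps)
  base <- target_mean + jitter - mean(droi)

  if (length(texture_shift) == 2L) texture_shift <- c(texture_shift, 0)
  afr <- params$texture_fine_frac[[cell_class]] + texture_shift[1L] +
    stats::rnorm(1L, 0, params$texture_cell_sd)
  bfr <- params$texture_coarse_frac[[cell_class]] + texture_shift[2L] +
    stats::rnorm(1L, 0, params$texture_cell_sd)
  qfr <- max(params$texture_impulse_frac[[cell_class]] + texture_shift[3L] +
               stats::rnorm(1L, 0, params$impulse_cell_sd), 0)
  z <- texture_field(n, n, afr, bfr, qfr, params$texture_impulse_amp,
                     params$texture_fine_sigma_px,
                     params$texture_coarse_sigma_px)
  cell_vals <- base + delta + noise_sd * z
  if (params$pixel_noise_model == "shot-like") {
    scale <- sqrt(pmax(base + delta, 1) / target_mean)
    cell_vals <- base + delta + noise_sd * z * scale
  }
  bg <- params$background_lifetime_ps +
    0.03 * params$background_lifetime_ps * matrix(stats::rnorm(n * n), n, n)
  m <- ifelse(foot, cell_vals, bg)
  m[m < 1] <- 1                     # lifetimes are strictly positive

  log$base_ps <- base; log$noise_sd_ps <- noise_sd; log$jitter_ps <- jitter
  log$texture_fine_frac <- afr; log$texture_coarse_frac <- bfr
  log$texture_impulse_frac <- qfr

  record <- data.frame(
    cell_id = sprintf("%s_seed%d", cell_class, seed),
    patient_id = NA_character_,
    group = if (cell_class == "control") "control" else "SCD",
    subtype = cell_class,
    shape_class = if (cell_class == "sickled") "sickled" else "round",
    roi_x0 = roi$x0, roi_y0 = roi$y0, roi_x1 = roi$x1, roi_y1 = roi$y1,
    path = NA_character_, stringsAsFactors = FALSE)

  list(matrix = m, record = record, roi = roi, log = log)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cohort of cells
#'
#' Builds a full study-shaped cohort: control patients contribute control
#' cells; SCD patients contribute non-sickled and (optionally) sickled
#' cells. The study layout is 27 control subjects and 45 SCD patients with
#' 10 control / 10 non-sickled / 5 sickled cells each. Every cell is drawn
#' from its own counter-based substream of \code{seed}, so cohorts are
#' bit-reproducible and insensitive to generation order.
#'
#' @param patients_per_group Named integer vector
#'   \code{c(control = ..., scd = ...)}.
#' @param cells_per_patient Named integer vector \code{c(control = ...,
#'   nonsickled = ..., sickled = ...)}: cells of each class per patient of
#'   the corresponding group (sickled may be 0).
#' @param params [flim_default_params()].
#' @param seed Master integer seed.
#' @param out_dir If non-NULL, matrices are written as TSV files under
#'   \code{out_dir/matrices} and the manifest as \code{out_dir/manifest.tsv}.
#' @return List of class \code{"flim_cohort"}: \code{manifest} (data frame),
#'   \code{cells} (list of generate_cell results, named by cell_id),
#'   \code{params}, \code{seed}.
#' @export
generate_cohort <- function(patients_per_group = c(control = 27L, scd = 45L),
                            cells_per_patient = c(control = 10L,
                                                  nonsickled = 10L,
                                                  sickled = 5L),
                            params = flim_default_params(),
                            seed = 1L, out_dir = NULL) {
  validate_gen_params(params)
  if (!all(c("control", "scd") %in% names(patients_per_group)))
    stop("patients_per_group must name 'control' and 'scd'")
  if (any(patients_per_group < 1L))
    stop("each requested group needs at least one patient")
  if (any(cells_per_patient[c("control", "nonsickled")] < 1L))
    stop("control and nonsickled cell counts per patient must be positive")

  plan <- list()
  for (i in seq_len(patients_per_group[["control"]]))
    plan[[length(plan) + 1L]] <- list(patient = sprintf("C%02d", i),
                                      group = "control", class = "control",
                                      n = cells_per_patient[["control"]])
  for (i in seq_len(patients_per_group[["scd"]])) {
    pid <- sprintf("P%02d", i)
    plan[[length(plan) + 1L]] <- list(patient = pid, group = "SCD",
                                      class = "nonsickled",
                                      n = cells_per_patient[["nonsickled"]])
    ns <- cells_per_patient[["sickled"]]
    if (!is.na(ns) && ns > 0L)
      plan[[length(plan) + 1L]] <- list(patient = pid, group = "SCD",
                                        class = "sickled", n = ns)
  }

  # per-patient texture shifts from dedicated substreams (offset 10^6)
  patients <- unique(vapply(plan, `[[`, character(1L), "patient"))
  shifts <- lapply(seq_along(patients), function(i) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(substream_seed(seed, 1000000L + i))
    c(stats::rnorm(2L, 0, params$texture_patient_sd),
      stats::rnorm(1L, 0, params$impulse_patient_sd))
  })
  names(shifts) <- patients

  cells <- list(); rows <- list(); counter <- 0L
  for (pl in plan) {
    for (j in seq_len(pl$n)) {
      counter <- counter + 1L
      cs <- substream_seed(seed, counter)
      cell <- generate_cell(pl$class, params, seed = cs,
                            texture_shift = shifts[[pl$patient]])
      cid <- sprintf("%s_%s_%02d", pl$patient, pl$class, j)
      cell$record$cell_id <- cid
      cell$record$patient_id <- pl$patient
      cells[[cid]] <- cell
      rows[[length(rows) + 1L]] <- cell$record
    }
  }
  manifest <- do.call(rbind, rows)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "matrices"), recursive = TRUE,
               showWarnings = FALSE)
    for (cid in manifest$cell_id) {
      rel <- file.path("matrices", paste0(cid, ".tsv"))
      write_lifetime_matrix(cells[[cid]]$matrix, file.path(out_dir, rel))
      manifest$path[manifest$cell_id == cid] <- rel
      cells[[cid]]$record$path <- rel
    }
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  }

  structure(list(manifest = manifest, cells = cells, params = params,
                 seed = seed), class = "flim_cohort")
}

#' @export
print.flim_cohort <- function(x, ...) {
  tb <- table(x$manifest$subtype)
  cat(sprintf("<flim_cohort: %d cells (%s), %d patients, seed %d>\n",
              nrow(x$manifest),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
              length(unique(x$manifest$patient_id)), x$seed))
  invisible(x)
}
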