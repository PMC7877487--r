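#' Configure the synthetic group effect
#'
#' Describes how the simulated ASD group differs from typical controls (TC),
#' how sites shift values, and how much subject-level variability to add.
#' Voxel values within region r are drawn from a Gamma distribution with
#' region-specific shape and scale; the group effect multiplies the scale of
#' affected regions by \code{exp(+shift_magnitude)} for the first member of
#' each affected pair and \code{exp(-shift_magnitude)} for the second, so the
#' edge between pair members carries maximal distributional signal (shifting
#' both regions identically would leave their mutual similarity unchanged).
#' \code{shift_magnitude = 0} makes the two groups identically distributed.
#'
#' @param affected_region_pairs List of length-2 integer vectors of region
#'   labels whose value distributions differ between groups.
#' @param shift_magnitude Non-negative log-scale shift applied to affected
#'   regions in the ASD group.
#' @param noise_sd Positive SD of the subject-level log-normal jitter on every
#'   region's Gamma scale (between-subject variability).
#' @param sites Named numeric vector: per-site additive offset on the Gamma
#'   scale of all regions (multisite heterogeneity, orthogonal to diagnosis).
#'
#' @return An object of class \code{effect_config}.
#' @export
effect_config <- function(affected_region_pairs = list(c(5L, 23L), c(12L, 41L), c(30L, 57L),
                                                       c(64L, 80L), c(72L, 95L), c(88L, 101L)),
                          shift_magnitude = 0.6,
                          noise_sd = 0.1,
                          sites = c(siteA = 0, siteB = 0.02, siteC = -0.02)) {
  if (shift_magnitude < 0) stop("shift_magnitude must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (shift_magnitude > 0 && length(affected_region_pairs) == 0) {
    stop("shift_magnitude > 0 requires a non-empty affected_region_pairs list")
  }
  if (length(affected_region_pairs) > 0 &&
    !all(vapply(affected_region_pairs, length, 1L) == 2L)) {
    stop("affected_region_pairs must be a list of label pairs")
  }
  if (is.null(names(sites)) || any(names(sites) == "")) {
    stop("sites must be a named numeric vector of per-site offsets")
  }
  structure(
    list(
      affected_region_pairs = lapply(affected_region_pairs, as.integer),
      shift_magnitude = shift_magnitude,
      noise_sd = noise_sd,
      sites = sites
    ),
    class = "effect_config"
  )
}

# Per-region signed shift exponents for the ASD group: +1 for the first
# member of each affected pair, -1 for the second (first assignment wins if a
# region recurs).
.region_shift_signs <- function(effect, n_regions) {
  s <- numeric(n_regions)
  for (pair in effect$affected_region_pairs) {
    if (any(pair > n_regions)) stop("affected region label exceeds atlas regions")
    if (s[pair[1]] == 0) s[pair[1]] <- 1
    if (s[pair[2]] == 0) s[pair[2]] <- -1
  }
  s
}

#' Simulate a multisite cohort of gray-matter volume maps
#'
#' Draws per-subject voxel values region-wise from Gamma distributions whose
#' scale parameters depend on diagnosis only within the affected regions of
#' \code{effect}, with additive per-site offsets and subject-level log-normal
#' jitter. Region base parameters (shape ~ 3, scale in [0.2, 0.4]) are drawn
#' once from the master seed, so cohorts are bit-reproducible; each subject
#' then draws from an independently derived seed stream.
#'
#' @param atlas A \code{parcellation_atlas}.
#' @param n_asd,n_tc Number of ASD and TC subjects (each >= 1).
#' @param effect An \code{effect_config}.
#' @param seed Integer master seed.
#'
#' @return A list with \code{gm_maps} (list of \code{gm_volume_map}: list of
#'   \code{subject_id} and 3D \code{values} array) and \code{phenotypes}
#'   (data.frame with columns subject_id, dx, site, age, sex).
#' @export
#' @examples
#' atlas <- generate_atlas(c(16, 16, 16), n_regions = 8, seed = 1)
#' eff <- effect_config(affected_region_pairs = list(c(1L, 2L)), shift_magnitude = 0.5)
#' cohort <- simulate_cohort(atlas, n_asd = 2, n_tc = 2, effect = eff, seed = 1)
#' cohort$phenotypes
simulate_cohort <- function(atlas, n_asd, n_tc, effect = effect_config(), seed = 1L) {
  stopifnot(inherits(atlas, "parcellation_atlas"), inherits(effect, "effect_config"))
  if (n_asd < 1 || n_tc < 1) stop("n_asd and n_tc must both be >= 1")
  n_regions <- atlas$n_regions
  lab <- as.integer(atlas$label_volume)
  vox_of_region <- split(seq_along(lab), lab)

  rng <- local_rng(derive_seed(seed, 0L))
  shape_r <- stats::runif(n_regions, 2.5, 3.5)
  scale_r <- stats::runif(n_regions, 0.2, 0.4)
  restore_rng(rng)

  signs <- .region_shift_signs(effect, n_regions)
  site_names <- names(effect$sites)
  n <- n_asd + n_tc
  dx <- c(rep("ASD", n_asd), rep("TC", n_tc))

  gm_maps <- vector("list", n)
  site <- character(n)
  age <- numeric(n)
  sex <- character(n)
  for (i in seq_len(n)) {
    srng <- local_rng(derive_seed(seed, i))
    site[i] <- site_names[1L + (i - 1L) %% length(site_names)]
    age[i] <- round(stats::runif(1, 8, 40), 1)
    sex[i] <- if (stats::runif(1) < 0.8) "M" else "F"
    theta <- scale_r + effect$sites[[site[i]]]
    if (dx[i] == "ASD" && effect$shift_magnitude > 0) {
      theta <- theta * exp(signs * effect$shift_magnitude)
    }
    theta <- theta * exp(stats::rnorm(n_regions, 0, effect$noise_sd))
    values <- numeric(length(lab))
    for (r in seq_len(n_regions)) {
      idx <- vox_of_region[[as.character(r)]]
      values[idx] <- stats::rgamma(length(idx), shape = shape_r[r], scale = theta[r])
    }
    restore_rng(srng)
    gm_maps[[i]] <- structure(
      list(
        subject_id = sprintf("sub-%04d", i),
        values = array(values, dim = dim(atlas$label_volume))
      ),
      class = "gm_volume_map"
    )
  }

  phenotypes <- data.frame(
    subject_id = vapply(gm_maps, `[[`, "", "subject_id"),
    dx = dx,
    site = site,
    age = age,
    sex = sex,
    stringsAsFactors = FALSE
  )
  list(gm_maps = gm_maps, phenotypes = phenotypes)
}

#' @export
print.gm_volume_map <- function(x, ...) {
  cat(sprintf(
    "<gm_volume_map> %s, %s grid, mean value %.3f\n",
    x$subject_id, paste(dim(x$values), collapse = "x"), mean(x$values)
  ))
  invisible(x)
}

#' Write a cohort to disk (NIfTI volumes + phenotype CSV)
#'
#' @param cohort Result of \code{\link{simulate_cohort}}.
#' @param dir Output directory (created if missing).
#' @param compress Write \code{.nii.gz} (default) or plain \code{.nii}.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, compress = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  for (gm in cohort$gm_maps) {
    RNifti::writeNifti(
      RNifti::asNifti(gm$values),
      file.path(dir, paste0(gm$subject_id, "_gm", ext))
    )
  }
  utils::write.csv(cohort$phenotypes,
    file.path(dir, "phenotypes.csv"),
    row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}

#' Read a gray-matter volume map from a NIfTI file
#'
#' @param path Path to the volume.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @return A \code{gm_volume_map}.
#' @export
read_gm_map <- function(path, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(subject_id)) {
    subject_id <- sub("_gm$", "", sub("\\.nii(\\.gz)?$", "", basename(path)))
  }
  structure(
    list(subject_id = subject_id, values = array(as.numeric(img), dim = dim(img))),
    class = "gm_volume_map"
  )
}
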