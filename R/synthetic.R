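# Synthetic planar-biaxial data and material variants.
#
# The study's own biaxial curves live in an appendix that is not part of the
# distributed text, so simulation studies here run on synthetic datasets
# generated from known GOH parameters with seeded multiplicative noise.

# evaluate code under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Planar-biaxial protocol specification
#'
#' Describes a family of stretch-controlled biaxial protocols: each protocol
#' ramps the circumferential and axial stretches from 1 in a fixed increment
#' ratio, the faster axis reaching `max_stretch`. Three ratio protocols
#' (1:1, 1:0.75, 0.75:1) are a typical planar-biaxial design for soft
#' tissue and are the default.
#'
#' @param ratios list of length-2 numeric vectors, the circumferential:axial
#'   stretch-increment ratios.
#' @param max_stretch peak stretch on the faster axis (> 1, default 1.30).
#' @param points stretch levels per protocol (>= 3, default 15).
#' @param cv coefficient of variation of the multiplicative Gaussian noise
#'   applied to stresses (>= 0; 0 gives exact model stresses).
#' @param seed integer RNG seed for the noise draw (NULL: use current RNG).
#' @return object of class `biaxial_protocol`.
#' @export
biaxial_protocol <- function(ratios = list(c(1, 1), c(1, 0.75), c(0.75, 1)),
                             max_stretch = 1.30, points = 15, cv = 0,
                             seed = NULL) {
  stopifnot(is.list(ratios), length(ratios) >= 1)
  if (!(max_stretch > 1)) stop("max_stretch must be > 1")
  if (points < 3) stop("points must be >= 3")
  if (cv < 0) stop("cv must be >= 0")
  out <- list(ratios = lapply(ratios, as.numeric), max_stretch = max_stretch,
              points = as.integer(points), cv = cv, seed = seed)
  class(out) <- "biaxial_protocol"
  out
}

#' Planar-biaxial dataset container
#'
#' A data frame of stretch pairs with measured in-plane Cauchy stresses,
#' grouped by protocol, with specimen metadata.
#'
#' @param records data.frame with columns `protocol`, `lambda_c`,
#'   `lambda_a`, `sigma_cc_pa`, `sigma_aa_pa`.
#' @param label specimen label.
#' @param region region tag (e.g. "mid", "distal").
#' @return object of class `biaxial_dataset` (a data.frame).
#' @export
biaxial_dataset <- function(records, label = "specimen", region = NA_character_) {
  need <- c("protocol", "lambda_c", "lambda_a", "sigma_cc_pa", "sigma_aa_pa")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records <- as.data.frame(records)[need]
  if (any(records$lambda_c < 1 - 1e-6) || any(records$lambda_a < 1 - 1e-6))
    stop("stretches must be >= 1 - 1e-6")
  if (!all(is.finite(records$sigma_cc_pa)) || !all(is.finite(records$sigma_aa_pa)))
    stop("stresses must be finite")
  structure(records, class = c("biaxial_dataset", "data.frame"),
            label = label, region = region)
}

#' Generate a synthetic biaxial dataset from known GOH parameters
#'
#' Stresses are the exact plane-stress model stresses multiplied by
#' `(1 + cv * z)` with `z` standard normal, drawn reproducibly from the
#' protocol seed. `cv = 0` returns exact model stresses.
#'
#' @param params generating [goh_params].
#' @param spec a [biaxial_protocol].
#' @return a [biaxial_dataset]; the generating parameters are kept in the
#'   `"generator"` attribute for reference.
#' @export
#' @examples
#' p <- aorta_materials("flap")$mid_flap_3
#' d <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0.02, seed = 17))
#' head(d)
generate_biaxial_dataset <- function(params, spec = biaxial_protocol()) {
  validate_goh_params(params)
  stopifnot(inherits(spec, "biaxial_protocol"))
  recs <- do.call(rbind, lapply(seq_along(spec$ratios), function(k) {
    r <- spec$ratios[[k]]
    f <- r / max(r)
    t <- seq_len(spec$points) / spec$points
    data.frame(protocol = k,
               lambda_c = 1 + t * (spec$max_stretch - 1) * f[1],
               lambda_a = 1 + t * (spec$max_stretch - 1) * f[2])
  }))
  sig <- biaxial_cauchy_stress(params, recs$lambda_c, recs$lambda_a)
  noise <- with_seed(spec$seed, {
    matrix(stats::rnorm(2 * nrow(recs), 0, 1), ncol = 2)
  })
  sig_n <- sig * (1 + spec$cv * noise)
  recs$sigma_cc_pa <- sig_n[, 1]
  recs$sigma_aa_pa <- sig_n[, 2]
  out <- biaxial_dataset(recs, label = params$label)
  attr(out, "generator") <- params
  attr(out, "protocol") <- spec
  out
}

#' Read and write biaxial dataset CSV files
#'
#' CSV layout: columns `protocol, lambda_c, lambda_a, sigma_cc_pa,
#' sigma_aa_pa`.
#'
#' @param path CSV path.
#' @param label,region metadata for the constructed dataset.
#' @return `read_biaxial_csv`: a [biaxial_dataset].
#' @export
read_biaxial_csv <- function(path, label = basename(path), region = NA_character_) {
  biaxial_dataset(utils::read.csv(path), label = label, region = region)
}

#' @rdname read_biaxial_csv
#' @param data a [biaxial_dataset].
#' @export
write_biaxial_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Seeded material-parameter variants for sensitivity studies
#'
#' Draws `n - 1` parameter sets uniformly within symmetric relative ranges
#' around a base set; the base itself is returned unperturbed as variant 1.
#' Used as documented surrogates for the unavailable per-sample wall
#' parameter variations.
#'
#' @param base a [goh_params].
#' @param rel_ranges named list of relative half-widths, e.g.
#'   `list(c10 = 0.2, k1 = 0.2)` for +/-20%. Only named fields are
#'   perturbed.
#' @param n total number of variants (including the base).
#' @param seed integer RNG seed.
#' @return list of [goh_params] of length `n`.
#' @export
generate_material_variants <- function(base, rel_ranges = list(c10 = 0.2, k1 = 0.2),
                                       n = 5, seed = 1) {
  validate_goh_params(base)
  stopifnot(n >= 1)
  fields <- names(rel_ranges)
  ok <- c("c10", "k1", "k2", "alpha", "kappa", "thickness")
  if (!all(fields %in% ok)) stop("unknown parameter fields: ",
                                 paste(setdiff(fields, ok), collapse = ", "))
  # bounds check on the extremes of each requested range
  for (f in fields) {
    r <- abs(rel_ranges[[f]])
    for (s in c(-1, 1)) {
      p <- base
      p[[f]] <- base[[f]] * (1 + s * r)
      res <- tryCatch({ validate_goh_params(p); NULL }, error = identity)
      if (!is.null(res))
        stop("range for '", f, "' violates parameter bounds: ",
             conditionMessage(res))
    }
  }
  vars <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (i == 1) return(base)
      p <- base
      for (f in fields) {
        r <- abs(rel_ranges[[f]])
        p[[f]] <- base[[f]] * (1 + stats::runif(1, -r, r))
      }
      p$label <- sprintf("%s_var%d", base$label, i - 1)
      validate_goh_params(p)
      p
    })
  })
  vars
}
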