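#' Default experimental calcium design
#'
#' Mimics skinned-muscle practice: 18 log-spaced concentrations over
#' [1, 10] uM spanning the transition region, plus 3 sub-threshold points
#' (0.05, 0.16, 0.5 uM) anchoring the zero-tension baseline.
#'
#' @return Ascending numeric vector of 21 concentrations, uM.
#' @export
default_ca_design <- function() {
  sort(c(0.05, 0.16, 0.5, exp(seq(log(1), log(10), length.out = 18))))
}

#' Generate a synthetic skinned-muscle calcium-tension dataset
#'
#' Emulates steady-state tension measurements at several sarcomere lengths:
#' noiseless curves from either the mechanochemical model or a Hill model,
#' plus i.i.d. Gaussian tension noise, clipped at zero (a skinned preparation
#' cannot report negative active tension). Reproducible under `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param model `"mechchem"` or `"hill"`.
#' @param params_per_sl Data frame with one row per sarcomere length: column
#'   `sl` plus (`c_f`, `c_s`, `k_tnca0`, optionally `n`) for `"mechchem"` or
#'   (`s_max`, `ec50`, `n_h`) for `"hill"`. See [reference_params()].
#' @param ca_design Calcium concentrations sampled at every sarcomere length,
#'   uM, within (0.001, 10].
#' @param noise_sigma Gaussian tension noise standard deviation, S (>= 0).
#' @param seed Integer seed (required when `noise_sigma > 0`).
#' @param thick_len,thin_len,bare_zone_len Filament geometry (mechchem model
#'   only).
#' @return Data frame with columns `sarcomere_length_um`, `calcium_uM`,
#'   `tension_S` and a `"provenance"` attribute recording the generator
#'   settings.
#' @examples
#' ds <- generate_dataset("hill", reference_params("hill"),
#'                        noise_sigma = 0.02, seed = 7)
#' head(ds)
#' @export
generate_dataset <- function(model = c("mechchem", "hill"), params_per_sl,
                             ca_design = default_ca_design(),
                             noise_sigma = 0.02, seed = NULL,
                             thick_len = 1.65, thin_len = 1.2,
                             bare_zone_len = 0.1) {
  model <- match.arg(model)
  stopifnot(is.data.frame(params_per_sl), "sl" %in% names(params_per_sl),
            is.numeric(ca_design), is.numeric(noise_sigma),
            length(noise_sigma) == 1L)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(ca_design <= 0.001 - 1e-12 | ca_design > 10 * (1 + 1e-12)))
    stop("ca_design must lie within (0.001, 10] uM")
  ca_design <- sort(ca_design)

  rows <- lapply(seq_len(nrow(params_per_sl)), function(i) {
    row <- params_per_sl[i, ]
    clean <- switch(model,
      mechchem = {
        geom <- sarcomere_geometry(row$sl, thick_len, thin_len, bare_zone_len)
        total_tension(.params_from_row(row), ca_design, geom)
      },
      hill = hill_tension(hill_params(row$s_max, row$ec50, row$n_h), ca_design))
    data.frame(sarcomere_length_um = row$sl, calcium_uM = ca_design,
               tension_S = clean)
  })
  out <- do.call(rbind, rows)

  if (noise_sigma > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sigma > 0")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    out$tension_S <- pmax(out$tension_S + stats::rnorm(nrow(out), 0, noise_sigma), 0)
  }
  rownames(out) <- NULL
  attr(out, "provenance") <- list(model = model,
                                  params = params_per_sl,
                                  ca_design = ca_design,
                                  noise_sigma = noise_sigma,
                                  seed = seed)
  out
}

#' Read / write calcium-tension datasets as CSV
#'
#' The on-disk contract is a CSV with header columns `sarcomere_length_um`,
#' `calcium_uM`, `tension_S`. `write_dataset` formats numbers at full double
#' precision (17 significant digits) so a write/read round trip is exact, and
#' drops a JSON provenance sidecar (`<path>.json`) when the dataset carries
#' generator provenance.
#'
#' @param path CSV file path.
#' @return `read_dataset` returns the dataset data frame; `write_dataset`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c("sarcomere_length_um", "calcium_uM", "tension_S")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) stop("empty dataset: ", path, " has a header but no rows")
  out <- data.frame(sarcomere_length_um = numeric(nrow(raw)),
                    calcium_uM = numeric(nrow(raw)),
                    tension_S = numeric(nrow(raw)))
  for (col in need) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric value in column ", col, " at data row ", bad[1L],
           " of ", path, " ('", raw[[col]][bad[1L]], "')")
    out[[col]] <- v
  }
  bad_ca <- which(out$calcium_uM <= 0)
  if (length(bad_ca))
    stop("non-positive calcium concentration at data row ", bad_ca[1L],
         " of ", path)
  out
}

#' @rdname read_dataset
#' @param ds Dataset data frame (see [generate_dataset()]).
#' @export
write_dataset <- function(ds, path) {
  stopifnot(is.data.frame(ds),
            all(c("sarcomere_length_um", "calcium_uM", "tension_S") %in% names(ds)))
  fmt <- ds[, c("sarcomere_length_um", "calcium_uM", "tension_S")]
  for (col in names(fmt)) fmt[[col]] <- sprintf("%.17g", fmt[[col]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  prov <- attr(ds, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}
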