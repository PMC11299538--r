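#' Read and write spike trains and spectra
#'
#' Plain-text interchange formats:
#' * spike timestamps: one integer millisecond per line (`.txt`);
#' * delta vectors: single-column CSV of 0/1 (`delta` header);
#' * trial matrices: headerless CSV, one trial per row;
#' * spectra: CSV with `freq_hz`, `power` and optional `significant`.
#'
#' @param train a `spike_train`.
#' @param path file path.
#' @return readers return the corresponding object; writers return the path
#'   invisibly.
#' @name spike_io
NULL

#' @rdname spike_io
#' @export
write_spike_times <- function(train, path) {
  writeLines(as.character(spike_times(train)), path)
  invisible(path)
}

#' @rdname spike_io
#' @param T train duration in ms (timestamp files do not carry it).
#' @export
read_spike_times <- function(path, T) {
  x <- scan(path, what = integer(), quiet = TRUE)
  spike_train_from_times(x, T)
}

#' @rdname spike_io
#' @export
write_delta_csv <- function(train, path) {
  write.csv(data.frame(delta = train$delta), path, row.names = FALSE)
  invisible(path)
}

#' @rdname spike_io
#' @export
read_delta_csv <- function(path) {
  df <- read.csv(path)
  if (!"delta" %in% names(df)) stop("no 'delta' column in ", path)
  new_spike_train(df$delta)
}

#' @rdname spike_io
#' @param trials a `trial_matrix`.
#' @export
write_trial_matrix_csv <- function(trials, path) {
  utils::write.table(as.matrix(trials), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname spike_io
#' @export
read_trial_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  structure(m, class = c("trial_matrix", "matrix", "array"))
}

#' @rdname spike_io
#' @param psd a `psd` object.
#' @param sig optional `significance_result` to flag searched bins.
#' @export
write_psd_csv <- function(psd, path, sig = NULL) {
  df <- data.frame(freq_hz = psd$freq, power = psd$power)
  if (!is.null(sig)) {
    flag <- integer(length(psd$freq))
    flag[match(sig$freq[sig$sig], psd$freq)] <- 1L
    df$significant <- flag
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname spike_io
#' @export
read_psd_csv <- function(path) {
  df <- read.csv(path)
  if (nrow(df) != 513L) stop("expected 513 rows, got ", nrow(df))
  new_psd(df$power, 1L)
}

#' Write significance metadata as JSON
#'
#' @param sig a `significance_result`.
#' @param path output path.
#' @param n_segments optional segment count to record.
#' @export
write_significance_json <- function(sig, path, n_segments = NULL) {
  jsonlite::write_json(
    list(alpha_c = sig$alpha_c, threshold = sig$threshold,
         hf_mean = sig$hf_mean, hf_sd = sig$hf_sd,
         n_segments = n_segments,
         significant_freqs_hz = sig$freq[sig$sig]),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a grid configuration from a YAML file
#'
#' Recognized keys: `T`, `f_osc`, and one of `p_base_offset` / `p_base`
#' (lists), `m` (list), plus scalars `n_r`, `k`, `reps`, `seed`,
#' `n_surrogates`.
#'
#' @param path YAML file path.
#' @return a [grid_config()] object.
#' @export
read_grid_config <- function(path) {
  y <- yaml::read_yaml(path)
  req <- c("T", "f_osc", "m")
  miss <- setdiff(req, names(y))
  if (length(miss)) stop("grid config missing: ", paste(miss, collapse = ", "))
  args <- list(T = unlist(y[["T"]]), f_osc = unlist(y[["f_osc"]]),
               m = unlist(y[["m"]]))
  if (!is.null(y[["p_base_offset"]]))
    args$p_base_offset <- unlist(y[["p_base_offset"]])
  if (!is.null(y[["p_base"]])) args$p_base <- unlist(y[["p_base"]])
  for (s in c("n_r", "k", "reps", "seed", "n_surrogates",
              "skip_m0_methods"))
    if (!is.null(y[[s]])) args[[s]] <- y[[s]]
  do.call(grid_config, args)
}
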