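#' Write an RMSD series to CSV
#'
#' Columns: `frame`, `time_ns`, `rmsd_nm`.
#'
#' @param x An `rmsd_series` from [backbone_rmsd_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rmsd_csv <- function(x, path) {
  utils::write.csv(data.frame(frame = seq_along(x$rmsd), time_ns = x$times,
                              rmsd_nm = x$rmsd),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.contact_summary <- function(x, ...) {
  data.frame(label = x$label, polar_total = x$polar_total, ionic = x$ionic,
             nonspecific = x$nonspecific, nonpolar = x$nonpolar,
             total = x$total, stringsAsFactors = FALSE)
}

#' Write contact records or summaries to CSV
#'
#' @param x A contact record data.frame from [interchain_contacts()] or a
#'   `contact_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contacts_csv <- function(x, path) {
  if (inherits(x, "contact_summary")) x <- as.data.frame(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write an order-parameter profile to CSV
#'
#' Columns: `region`, `carbon_index`, `abs_scd`, `n_lipids`.
#'
#' @param x data.frame from [scd_profile()] or [scd_region_profiles()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scd_csv <- function(x, path) {
  utils::write.csv(x[, c("region", "carbon_index", "abs_scd", "n_lipids")],
                   path, row.names = FALSE)
  invisible(path)
}
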