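#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own RNG stream from the
#' run seed plus a stage label, so stages can be re-run or reordered without
#' perturbing each other. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483647)
}

#' Structured log message
#'
#' @param ... message parts passed to [sprintf()]-free paste.
#' @param verbose emit or stay silent.
#' @keywords internal
dr_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message("[deltaradiomics ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
  }
  invisible(NULL)
}

# stable checksum of a data.frame written as CSV text (provenance logging)
dr_checksum <- function(df) {
  con <- textConnection("chk", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  sum(utf8ToInt(paste(chk, collapse = "\n"))) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
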