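#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals, as used for
#' printed percentages. Base R's [round()] rounds half to even, which would
#' turn 90.15 into 90.1 or 90.2 depending on the binary representation.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values intended as exact halves
  # (e.g. 0.125 stored as 0.12499999...) round up
  sign(x) * floor(abs(x) * m + 0.5 + .Machine$double.eps * abs(x) * m) / m
}

# FNV-1a 32-bit over a character scalar; used for config hashes in manifests.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte since b < 256; keeps h a double in
    # [0, 2^32) clear of bitwXor's 32-bit signed limit
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403;
    # (h * 2^24) mod 2^32 reduces to (h mod 2^8) * 2^24, keeping every
    # intermediate below 2^53 so double arithmetic stays exact
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# configuration/contract violations get their own condition class so the CLI
# can distinguish exit code 1 (bad config) from 2 (stage failure)
stop_cfg <- function(...) {
  stop(structure(class = c("faersignal_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# upper-case, trim, collapse internal whitespace
squash_upper <- function(x) {
  x <- toupper(trimws(x))
  gsub("[[:space:]]+", " ", x)
}
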