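#' Build a 10-20 style EEG montage
#'
#' Constructs a synthetic electrode layout following the 10-20 / 10-10 naming
#' convention, projected onto the 2D head plane (closed unit disc, nasion at
#' the top, left hemisphere at negative x). Odd numeric suffixes denote
#' left-hemisphere electrodes, even suffixes their right-hemisphere mirrors,
#' and a trailing "z" the midline. Positions are generated algorithmically on
#' concentric arcs rather than copied from a digitized cap, so left/right
#' pairs mirror each other exactly: for every left channel the matching right
#' channel has its x coordinate negated.
#'
#' @param n_channels Number of electrodes; one of 8, 32 (32-channel
#'   emotion-recognition style cap) or 64 (64-channel auditory-attention
#'   style cap).
#' @return An object of class `montage`: a list with `channel_names`
#'   (character) and `positions` (n x 2 matrix of head-plane coordinates,
#'   rows named by channel).
#' @examples
#' m <- make_montage(8)
#' m$channel_names
#' @export
make_montage <- function(n_channels) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 ||
      !n_channels %in% c(8, 32, 64)) {
    stop("`n_channels` must be one of 8, 32, 64", call. = FALSE)
  }
  tab <- montage_table()
  names_wanted <- switch(as.character(n_channels),
    "8"  = c("F3", "F4", "T7", "T8", "P3", "P4", "O1", "O2"),
    "32" = c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5",
             "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4",
             "Fz", "F4", "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6",
             "CP2", "P4", "P8", "PO4", "O2"),
    "64" = c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5",
             "FC3", "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3",
             "CP1", "P1", "P3", "P5", "P7", "P9", "PO7", "PO3", "O1",
             "Iz", "Oz", "POz", "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4",
             "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6", "FC4",
             "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
             "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4",
             "O2"))
  missing <- setdiff(names_wanted, rownames(tab))
  if (length(missing) > 0) {
    stop("internal montage table lacks: ", paste(missing, collapse = ", "))
  }
  pos <- tab[names_wanted, , drop = FALSE]
  out <- list(channel_names = names_wanted, positions = pos)
  class(out) <- "montage"
  validate_montage(out)
  out
}

# Full 10-10 style coordinate table. Rows of electrodes front-to-back at
# fixed y levels; lateral offsets proportional to the electrode number
# (1/2 -> 0.25, 3/4 -> 0.5, 5/6 -> 0.75, 7/8 -> 1.0, 9/10 -> 1.25 of the
# row half-width), scaled so all positions stay inside the unit disc.
montage_table <- function() {
  rows <- list(
    list(prefix = "Fp", y =  0.85, idx = c(1, 0, 2)),
    list(prefix = "AF", y =  0.68, idx = c(7, 3, 0, 4, 8)),
    list(prefix = "F",  y =  0.50, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    list(prefix = "FC", y =  0.25, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    list(prefix = "C",  y =  0.00, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    list(prefix = "CP", y = -0.25, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    list(prefix = "P",  y = -0.50, idx = c(9, 7, 5, 3, 1, 0, 2, 4, 6, 8, 10)),
    list(prefix = "PO", y = -0.68, idx = c(7, 3, 0, 4, 8)),
    list(prefix = "O",  y = -0.85, idx = c(1, 0, 2)),
    list(prefix = "I",  y = -0.95, idx = c(0))
  )
  # 10-20 temporal / frontotemporal names replace the 7/8 slots of their rows
  special <- c("FC7" = "FT7", "FC8" = "FT8", "C7" = "T7", "C8" = "T8",
               "CP7" = "TP7", "CP8" = "TP8")
  out <- list()
  for (r in rows) {
    hw <- 0.75 * sqrt(1 - r$y^2)  # row half-width inside the disc
    for (k in r$idx) {
      nm <- if (k == 0) paste0(r$prefix, "z") else paste0(r$prefix, k)
      if (nm %in% names(special)) nm <- special[[nm]]
      s <- if (k == 0) 0 else 0.25 * ceiling(k / 2) * ifelse(k %% 2 == 1, -1, 1)
      p <- c(s * hw, r$y)
      nrm <- sqrt(sum(p^2))
      if (nrm > 0.98) p <- p * 0.98 / nrm  # clamp rim electrodes into the disc
      out[[nm]] <- p
    }
  }
  m <- do.call(rbind, out)
  rownames(m) <- names(out)
  colnames(m) <- c("x", "y")
  m
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "montage"))
  if (anyDuplicated(m$channel_names)) stop("montage channel names must be unique")
  if (length(m$channel_names) < 4) stop("montage needs at least 4 channels")
  r <- sqrt(rowSums(m$positions^2))
  if (any(r > 1 + 1e-12)) stop("montage positions must lie in the closed unit disc")
  invisible(m)
}

#' Hemisphere of each channel from its 10-20 name
#'
#' Odd numeric suffix -> "left", even -> "right", trailing "z" -> "midline".
#'
#' @param channel_names Character vector of 10-20 style names.
#' @return Character vector in `c("left", "right", "midline")`.
#' @export
channel_hemisphere <- function(channel_names) {
  suf <- sub("^[A-Za-z]+", "", channel_names)
  vapply(suf, function(s) {
    if (s == "" || s == "z") return("midline")
    if (as.integer(s) %% 2 == 1) "left" else "right"
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channel_names), " channels: ",
      paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
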