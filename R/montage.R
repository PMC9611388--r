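#' Electrode montages with 2-D scalp positions and named region groups
#'
#' Builds a bundled montage: electrode labels from the extended 10-10
#' nomenclature placed on a schematic unit-disc head (nose up, left ear at
#' negative x).  Positions are a standard top-view projection suitable for
#' topographies and nearest-neighbour (Hjorth) surface-Laplacian operators;
#' they are not digitised head coordinates.
#'
#' Region groups attached to the montage (configurable via [montage_regions]):
#' \describe{
#'   \item{OCC_SEED}{occipital seed set Oz, O1, O2, POz, PO3, PO4 whose
#'     average forms the virtual seed channel for connectivity}
#'   \item{BA}{left inferior-frontal set F5, F7, FC5, FT7}
#'   \item{LS / RS}{left / right somatosensory sets (C5, CP3, CP5 and mirror)}
#'   \item{RF, LCS, RCS, RAG, CF, LAG}{right-frontal, left/right central
#'     sulcus, right/left angular gyrus and central frontal groups}
#' }
#'
#' @param preset one of `"paper64"` (64-channel 10-10 set) or `"demo21"`
#'   (21-channel subset for fast examples; keeps the full occipital seed).
#' @return an object of class `eeg_montage`: a data frame with columns
#'   `channel`, `x`, `y` and a `regions` attribute (named list of label
#'   vectors).
#' @examples
#' m <- generate_montage("paper64")
#' montage_regions(m)$OCC_SEED
#' @export
generate_montage <- function(preset = "paper64") {
  presets <- c("paper64", "demo21")
  if (!is.character(preset) || length(preset) != 1L || !(preset %in% presets)) {
    stop("unknown montage preset ", deparse(preset),
         "; available presets: ", paste(presets, collapse = ", "),
         call. = FALSE)
  }
  full <- montage_table_1010()
  if (preset == "paper64") {
    tab <- full
    regions <- list(
      OCC_SEED = c("Oz", "O1", "O2", "POz", "PO3", "PO4"),
      BA  = c("F5", "F7", "FC5", "FT7"),
      LS  = c("C5", "CP3", "CP5"),
      RS  = c("C6", "CP4", "CP6"),
      RF  = c("F4", "F6", "F8", "FC4", "FC6"),
      LCS = c("C1", "C3"),
      RCS = c("C2", "C4"),
      RAG = c("P4", "P6"),
      LAG = c("P3", "P5"),
      CF  = c("F1", "Fz", "F2", "FCz")
    )
  } else {
    keep <- c("Fp1", "Fpz", "Fp2", "F5", "Fz", "F6", "C3", "Cz", "C4",
              "CP3", "CP4", "P3", "P4", "PO7", "PO3", "POz", "PO4", "PO8",
              "O1", "Oz", "O2")
    tab <- full[match(keep, full$channel), ]
    regions <- list(
      OCC_SEED = c("Oz", "O1", "O2", "POz", "PO3", "PO4"),
      BA  = "F5", RF = "F6",
      LS  = "CP3", RS = "CP4",
      LCS = "C3", RCS = "C4",
      RAG = "P4", LAG = "P3",
      CF  = "Fz"
    )
  }
  rownames(tab) <- NULL
  structure(tab, regions = regions, preset = preset,
            class = c("eeg_montage", "data.frame"))
}

# Schematic top-view 10-10 coordinate table (64 labels).
montage_table_1010 <- function() {
  rows <- list(
    list(y = 0.85, labels = c("Fp1", "Fpz", "Fp2"),
         pos = c(-1, 0, 1)),
    list(y = 0.65, labels = c("AF7", "AF3", "AFz", "AF4", "AF8"),
         pos = c(-4, -2, 0, 2, 4)),
    list(y = 0.45,
         labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
         pos = -4:4),
    list(y = 0.25,
         labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
         pos = -4:4),
    list(y = 0.00,
         labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
         pos = -4:4),
    list(y = -0.25,
         labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
         pos = -4:4),
    list(y = -0.45,
         labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
         pos = -4:4),
    list(y = -0.65, labels = c("PO7", "PO3", "POz", "PO4", "PO8"),
         pos = c(-4, -2, 0, 2, 4)),
    list(y = -0.85, labels = c("O1", "Oz", "O2"), pos = c(-1, 0, 1))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(channel = r$labels,
               x = 0.95 * (r$pos / 4) * sqrt(1 - r$y^2),
               y = r$y, stringsAsFactors = FALSE)
  }))
  extra <- data.frame(channel = c("P9", "P10", "Iz"),
                      x = c(-0.80, 0.80, 0),
                      y = c(-0.55, -0.55, -0.97), stringsAsFactors = FALSE)
  rbind(out, extra)
}

#' Named electrode region groups of a montage
#' @param montage an `eeg_montage`
#' @return named list of character vectors of channel labels
#' @export
montage_regions <- function(montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  attr(montage, "regions")
}

#' Replace or extend region groups of a montage
#' @param montage an `eeg_montage`
#' @param ... named character vectors of channel labels
#' @return the montage with updated region groups
#' @export
set_montage_regions <- function(montage, ...) {
  stopifnot(inherits(montage, "eeg_montage"))
  new <- list(...)
  regs <- attr(montage, "regions")
  for (nm in names(new)) {
    missing <- setdiff(new[[nm]], montage$channel)
    if (length(missing)) {
      stop("region ", nm, " references channels not in montage: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    regs[[nm]] <- new[[nm]]
  }
  attr(montage, "regions") <- regs
  montage
}

# k nearest neighbours of every channel (indices + inverse-distance weights).
montage_neighbors <- function(montage, k = 4L) {
  xy <- as.matrix(montage[, c("x", "y")])
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  lapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    ord <- ord[ord != i]
    use <- ord[seq_len(min(k, length(ord)))]
    list(idx = use, w = 1 / d[i, use])
  })
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> preset ", attr(x, "preset") %||% "custom", ": ",
      nrow(x), " channels, ", length(attr(x, "regions")),
      " region groups\n", sep = "")
  cat("regions:", paste(names(attr(x, "regions")), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.eeg_montage <- function(x, labels = TRUE, ...) {
  graphics::plot(x$x, x$y, asp = 1, pch = 19, cex = 0.5,
                 xlab = "", ylab = "", axes = FALSE, ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  if (labels) graphics::text(x$x, x$y, x$channel, pos = 3, cex = 0.6)
  invisible(x)
}
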