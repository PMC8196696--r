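# Glyph renderer: turns a frame scene into an 8-bit-equivalent RGB array.
#
# Each category is drawn as a flat-colored glyph (rectangle or inscribed
# ellipse) inside its box, over a uniform background. Colors are distinct
# per category so desk-scale region proposal can separate overlapping
# objects (a pill inside an open mouth, a mouth on a face).

BACKGROUND_COLOR_ <- c(0.82, 0.82, 0.80)

categoryStyle_ <- function() {
  list(
    bottle      = list(col = c(0.85, 0.45, 0.10), shape = "rect"),
    cap         = list(col = c(0.95, 0.85, 0.10), shape = "ellipse"),
    cup         = list(col = c(0.10, 0.45, 0.85), shape = "rect"),
    face        = list(col = c(0.95, 0.80, 0.65), shape = "ellipse"),
    hand        = list(col = c(0.72, 0.54, 0.38), shape = "rect"),
    mouth       = list(col = c(0.75, 0.15, 0.20), shape = "ellipse"),
    open_bottle = list(col = c(0.55, 0.25, 0.05), shape = "rect"),
    open_mouth  = list(col = c(0.35, 0.05, 0.12), shape = "ellipse"),
    pill        = list(col = c(1.00, 1.00, 1.00), shape = "ellipse")
  )
}

# painter's order: large background objects first, pill last so it stays
# visible inside the open mouth
zOrder_ <- function() {
  c("face", "hand", "bottle", "open_bottle", "cup", "cap",
    "mouth", "open_mouth", "pill")
}

#' Render a frame scene to an RGB image
#'
#' Deterministically draws every placed object as a distinct flat-colored
#' glyph inside its bounding box over a uniform background.
#'
#' @param scene A frame scene (list with a `placements` data frame), as
#'   returned by [frameScene()].
#' @param width,height Output size in pixels (each >= 32).
#' @return Numeric array `height x width x 3` with values in `[0, 1]`.
#' @examples
#' ep <- sampleEpisode(defaultGrammar(), "medication", seed = 1)
#' img <- renderFrame(frameScene(ep, 1), 128, 128)
#' dim(img)
#' @export
renderFrame <- function(scene, width = 128, height = 128) {
  if (width < 32 || height < 32) {
    stop("frame must be at least 32x32 pixels", call. = FALSE)
  }
  pl <- scene$placements
  img <- array(rep(BACKGROUND_COLOR_, each = height * width),
               dim = c(height, width, 3))
  if (is.null(pl) || nrow(pl) == 0L) return(img)
  validateBoxes_(pl)
  if (any(pl$x_max > width) || any(pl$y_max > height)) {
    stop("placement box outside frame bounds", call. = FALSE)
  }
  assertCategory_(pl$category)
  styles <- categoryStyle_()
  ord <- order(match(pl$category, zOrder_()))
  for (k in ord) {
    st <- styles[[pl$category[k]]]
    x0 <- pl$x_min[k]; x1 <- pl$x_max[k]
    y0 <- pl$y_min[k]; y1 <- pl$y_max[k]
    cols <- seq(x0 + 1L, x1)        # 1-based pixel columns
    rows <- seq(y0 + 1L, y1)
    if (st$shape == "rect") {
      for (ch in 1:3) img[rows, cols, ch] <- st$col[ch]
    } else {
      cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
      rx <- (x1 - x0) / 2; ry <- (y1 - y0) / 2
      xs <- (cols - 0.5 - cx) / rx
      ys <- (rows - 0.5 - cy) / ry
      inside <- outer(ys^2, xs^2, `+`) <= 1
      for (ch in 1:3) {
        sub <- img[rows, cols, ch]
        sub[inside] <- st$col[ch]
        img[rows, cols, ch] <- sub
      }
    }
  }
  img
}

#' Render all frames of an episode
#'
#' @param episode An [Episode-class].
#' @return List of `height x width x 3` arrays, one per frame.
#' @export
renderEpisode <- function(episode) {
  sz <- frameSize(episode)
  lapply(episode@frames, renderFrame, width = sz[1], height = sz[2])
}

#' Write an episode's frames as PNG files
#'
#' Files are named `frame_0000.png`, `frame_0001.png`, ... (0-based) in
#' `dir`.
#'
#' @param episode An [Episode-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
writeEpisodeFrames <- function(episode, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sz <- frameSize(episode)
  paths <- character(nFrames(episode))
  for (i in seq_len(nFrames(episode))) {
    img <- renderFrame(episode@frames[[i]], sz[1], sz[2])
    paths[i] <- file.path(dir, sprintf("frame_%04d.png", i - 1L))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
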