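# Minimal 5x7 bitmap font for label overlays. Each glyph is 7 rows of
# 5-bit patterns (MSB = leftmost pixel). Unknown characters render as a
# filled box so label extents stay deterministic.

.font5x7 <- list(
  " " = c(0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00),
  "0" = c(0x0E, 0x11, 0x13, 0x15, 0x19, 0x11, 0x0E),
  "1" = c(0x04, 0x0C, 0x04, 0x04, 0x04, 0x04, 0x0E),
  "2" = c(0x0E, 0x11, 0x01, 0x02, 0x04, 0x08, 0x1F),
  "3" = c(0x1F, 0x02, 0x04, 0x02, 0x01, 0x11, 0x0E),
  "4" = c(0x02, 0x06, 0x0A, 0x12, 0x1F, 0x02, 0x02),
  "5" = c(0x1F, 0x10, 0x1E, 0x01, 0x01, 0x11, 0x0E),
  "6" = c(0x06, 0x08, 0x10, 0x1E, 0x11, 0x11, 0x0E),
  "7" = c(0x1F, 0x01, 0x02, 0x04, 0x08, 0x08, 0x08),
  "8" = c(0x0E, 0x11, 0x11, 0x0E, 0x11, 0x11, 0x0E),
  "9" = c(0x0E, 0x11, 0x11, 0x0F, 0x01, 0x02, 0x0C),
  "A" = c(0x0E, 0x11, 0x11, 0x1F, 0x11, 0x11, 0x11),
  "B" = c(0x1E, 0x11, 0x11, 0x1E, 0x11, 0x11, 0x1E),
  "C" = c(0x0E, 0x11, 0x10, 0x10, 0x10, 0x11, 0x0E),
  "D" = c(0x1C, 0x12, 0x11, 0x11, 0x11, 0x12, 0x1C),
  "E" = c(0x1F, 0x10, 0x10, 0x1E, 0x10, 0x10, 0x1F),
  "F" = c(0x1F, 0x10, 0x10, 0x1E, 0x10, 0x10, 0x10),
  "G" = c(0x0E, 0x11, 0x10, 0x17, 0x11, 0x11, 0x0F),
  "H" = c(0x11, 0x11, 0x11, 0x1F, 0x11, 0x11, 0x11),
  "I" = c(0x0E, 0x04, 0x04, 0x04, 0x04, 0x04, 0x0E),
  "J" = c(0x07, 0x02, 0x02, 0x02, 0x02, 0x12, 0x0C),
  "K" = c(0x11, 0x12, 0x14, 0x18, 0x14, 0x12, 0x11),
  "L" = c(0x10, 0x10, 0x10, 0x10, 0x10, 0x10, 0x1F),
  "M" = c(0x11, 0x1B, 0x15, 0x15, 0x11, 0x11, 0x11),
  "N" = c(0x11, 0x19, 0x15, 0x13, 0x11, 0x11, 0x11),
  "O" = c(0x0E, 0x11, 0x11, 0x11, 0x11, 0x11, 0x0E),
  "P" = c(0x1E, 0x11, 0x11, 0x1E, 0x10, 0x10, 0x10),
  "Q" = c(0x0E, 0x11, 0x11, 0x11, 0x15, 0x12, 0x0D),
  "R" = c(0x1E, 0x11, 0x11, 0x1E, 0x14, 0x12, 0x11),
  "S" = c(0x0F, 0x10, 0x10, 0x0E, 0x01, 0x01, 0x1E),
  "T" = c(0x1F, 0x04, 0x04, 0x04, 0x04, 0x04, 0x04),
  "U" = c(0x11, 0x11, 0x11, 0x11, 0x11, 0x11, 0x0E),
  "V" = c(0x11, 0x11, 0x11, 0x11, 0x11, 0x0A, 0x04),
  "W" = c(0x11, 0x11, 0x11, 0x15, 0x15, 0x1B, 0x11),
  "X" = c(0x11, 0x11, 0x0A, 0x04, 0x0A, 0x11, 0x11),
  "Y" = c(0x11, 0x11, 0x0A, 0x04, 0x04, 0x04, 0x04),
  "Z" = c(0x1F, 0x01, 0x02, 0x04, 0x08, 0x10, 0x1F),
  ":" = c(0x00, 0x04, 0x04, 0x00, 0x04, 0x04, 0x00),
  "." = c(0x00, 0x00, 0x00, 0x00, 0x00, 0x0C, 0x0C),
  "-" = c(0x00, 0x00, 0x00, 0x1F, 0x00, 0x00, 0x00),
  "+" = c(0x00, 0x04, 0x04, 0x1F, 0x04, 0x04, 0x00),
  "'" = c(0x04, 0x04, 0x08, 0x00, 0x00, 0x00, 0x00)
)
.font_unknown <- c(0x1F, 0x1F, 0x1F, 0x1F, 0x1F, 0x1F, 0x1F)

# draw one text string into an image at pixel (px, py) = top-left corner
draw_text <- function(img, text, px, py, color = c(1, 1, 0)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  chars <- strsplit(toupper(text), "")[[1]]
  x0 <- px
  for (ch in chars) {
    glyph <- .font5x7[[ch]] %||% .font_unknown
    for (row in 1:7) {
      bits <- glyph[row]
      for (col in 1:5) {
        if (bitwAnd(bits, bitwShiftL(1L, 5L - col)) != 0) {
          yy <- py + row - 1; xx <- x0 + col - 1
          if (yy >= 1 && yy <= h && xx >= 1 && xx <= w) {
            img[yy, xx, ] <- color
          }
        }
      }
    }
    x0 <- x0 + 6  # 5 px glyph + 1 px spacing
  }
  img
}
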