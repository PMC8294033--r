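# Minimal DICOM reader: uncompressed little-endian transfer syntaxes
# (explicit 1.2.840.10008.1.2.1 and implicit 1.2.840.10008.1.2), single- or
# multi-frame monochrome images. Enough to recover Rows/Columns/PixelSpacing/
# PixelData from cine exports; anything compressed or big-endian is rejected.

uint_le <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1))

read_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132)
  assert_that(length(preamble) == 132 &&
                rawToChar(preamble[129:132]) == "DICM",
              sprintf("'%s' is not a DICOM part-10 file", path))

  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  tags <- list()
  explicit <- TRUE  # file meta group is always explicit VR little endian
  repeat {
    hdr <- readBin(con, "raw", 4)
    if (length(hdr) < 4) break
    group <- uint_le(hdr[1:2])
    elem <- uint_le(hdr[3:4])
    if (explicit || group == 2L) {
      vr <- rawToChar(readBin(con, "raw", 2))
      if (vr %in% long_vrs) {
        readBin(con, "raw", 2)  # reserved
        len <- uint_le(readBin(con, "raw", 4))
      } else {
        len <- uint_le(readBin(con, "raw", 2))
      }
    } else {
      vr <- NA_character_
      len <- uint_le(readBin(con, "raw", 4))
    }
    assert_that(len < 0xFFFFFFFF,
                "undefined-length (encapsulated/sequence) elements unsupported")
    key <- sprintf("%04x,%04x", group, elem)
    payload <- readBin(con, "raw", len)
    tags[[key]] <- payload
    if (group == 2L && elem == 0x0010) {
      ts <- trimws(rawToChar(payload[payload != as.raw(0)]))
      assert_that(ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"),
                  sprintf("unsupported transfer syntax '%s'", ts))
      explicit <- ts == "1.2.840.10008.1.2.1"
    }
    if (group == 0x7FE0 && elem == 0x0010) break
  }

  us <- function(key) if (is.null(tags[[key]])) NULL else uint_le(tags[[key]][1:2])
  str <- function(key) {
    if (is.null(tags[[key]])) return(NULL)
    v <- tags[[key]]
    trimws(rawToChar(v[v != as.raw(0)]))
  }

  rows <- us("0028,0010")
  cols <- us("0028,0011")
  bits <- us("0028,0100") %||% 16L
  assert_that(!is.null(rows) && !is.null(cols), "missing Rows/Columns")
  assert_that(bits %in% c(8L, 16L), "only 8- or 16-bit pixel data supported")
  n_frames <- as.integer(str("0028,0008") %||% "1")
  spacing <- NULL
  if (!is.null(tags[["0028,0030"]])) {
    # PixelSpacing is "row\col" in mm
    spacing <- as.numeric(strsplit(str("0028,0030"), "\\\\")[[1]])
  }

  pd <- tags[["7fe0,0010"]]
  assert_that(!is.null(pd), "missing PixelData")
  vals <- if (bits == 8L) as.integer(pd) else {
    readBin(pd, "integer", n = length(pd) / 2, size = 2, endian = "little",
            signed = FALSE)
  }
  per_frame <- rows * cols
  assert_that(length(vals) >= per_frame * n_frames, "truncated PixelData")
  frames <- lapply(seq_len(n_frames), function(f) {
    v <- vals[((f - 1) * per_frame + 1):(f * per_frame)]
    matrix(v, nrow = rows, ncol = cols, byrow = TRUE)  # DICOM is row-major
  })
  list(frames = frames, n_frames = n_frames, pixel_spacing = spacing,
       rows = rows, cols = cols, bits = bits)
}
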