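# Minimal MessagePack encoder/decoder for the document tree.
#
# Covers the subset of the MessagePack specification the serialized tree
# uses: nil, booleans, integers, float64, UTF-8 strings, arrays and
# string-keyed maps. Doubles are always encoded as float64, so every
# finite (and non-finite) double round-trips bit-exactly. Written here
# because the format is needed for the binary model encoding.

msgpack_pack <- function(x) {
  buf <- raw(0)
  emit <- function(r) buf <<- c(buf, r)
  pack <- function(v) {
    if (is.null(v)) {
      emit(as.raw(0xc0))
    } else if (is.list(v)) {
      nms <- names(v)
      if (!is.null(nms)) {
        pack_len(length(v), 0x80, 0xde, 0xdf)
        for (i in seq_along(v)) {
          pack_str(nms[i])
          pack(v[[i]])
        }
      } else {
        pack_len(length(v), 0x90, 0xdc, 0xdd)
        for (el in v) pack(el)
      }
    } else if (is.character(v)) {
      stopifnot(length(v) == 1L)
      pack_str(v)
    } else if (is.logical(v)) {
      stopifnot(length(v) == 1L)
      emit(as.raw(if (isTRUE(v)) 0xc3 else 0xc2))
    } else if (is.integer(v)) {
      stopifnot(length(v) == 1L)
      emit(as.raw(0xd2))                       # int32
      emit(writeBin(v, raw(), size = 4L, endian = "big"))
    } else if (is.numeric(v)) {
      stopifnot(length(v) == 1L)
      emit(as.raw(0xcb))                       # float64
      emit(writeBin(as.numeric(v), raw(), size = 8L, endian = "big"))
    } else {
      stop(sprintf("msgpack: cannot encode type '%s'", typeof(v)),
           call. = FALSE)
    }
  }
  pack_len <- function(n, fix_base, tag16, tag32) {
    if (n < 16L) {
      emit(as.raw(bitwOr(fix_base, n)))
    } else if (n < 65536L) {
      emit(as.raw(tag16))
      emit(writeBin(as.integer(n), raw(), size = 2L, endian = "big"))
    } else {
      emit(as.raw(tag32))
      emit(writeBin(as.integer(n), raw(), size = 4L, endian = "big"))
    }
  }
  pack_str <- function(s) {
    b <- charToRaw(enc2utf8(s))
    n <- length(b)
    if (n < 32L) {
      emit(as.raw(bitwOr(0xa0, n)))
    } else if (n < 256L) {
      emit(as.raw(c(0xd9, n)))
    } else if (n < 65536L) {
      emit(as.raw(0xda))
      emit(writeBin(as.integer(n), raw(), size = 2L, endian = "big"))
    } else {
      emit(as.raw(0xdb))
      emit(writeBin(as.integer(n), raw(), size = 4L, endian = "big"))
    }
    emit(b)
  }
  pack(x)
  buf
}

msgpack_unpack <- function(raw_bytes) {
  pos <- 1L
  take <- function(n) {
    if (pos + n - 1L > length(raw_bytes))
      stop("msgpack: truncated input", call. = FALSE)
    r <- raw_bytes[pos:(pos + n - 1L)]
    pos <<- pos + n
    r
  }
  read_uint <- function(n) {
    b <- as.integer(take(n))
    v <- 0
    for (x in b) v <- v * 256 + x
    v
  }
  unpack <- function() {
    tag <- as.integer(take(1L))
    if (tag <= 0x7f) return(tag)                       # positive fixint
    if (tag >= 0xe0) return(tag - 256L)                # negative fixint
    if (tag >= 0xa0 && tag <= 0xbf) return(read_str(tag - 0xa0))
    if (tag >= 0x90 && tag <= 0x9f) return(read_arr(tag - 0x90))
    if (tag >= 0x80 && tag <= 0x8f) return(read_map(tag - 0x80))
    switch(as.character(tag),
      "192" = NULL,                                    # nil
      "194" = FALSE,
      "195" = TRUE,
      "203" = readBin(take(8L), "double", size = 8L, endian = "big"),
      "202" = readBin(take(4L), "double", size = 4L, endian = "big"),
      "204" = read_uint(1L),
      "205" = read_uint(2L),
      "206" = read_uint(4L),
      "208" = readBin(take(1L), "integer", size = 1L, signed = TRUE),
      "209" = readBin(take(2L), "integer", size = 2L, signed = TRUE,
                      endian = "big"),
      "210" = readBin(take(4L), "integer", size = 4L, endian = "big"),
      "217" = read_str(read_uint(1L)),
      "218" = read_str(read_uint(2L)),
      "219" = read_str(read_uint(4L)),
      "220" = read_arr(read_uint(2L)),
      "221" = read_arr(read_uint(4L)),
      "222" = read_map(read_uint(2L)),
      "223" = read_map(read_uint(4L)),
      stop(sprintf("msgpack: unsupported tag 0x%02x", tag), call. = FALSE)
    )
  }
  read_str <- function(n) {
    s <- rawToChar(take(n))
    Encoding(s) <- "UTF-8"
    s
  }
  read_arr <- function(n) {
    out <- vector("list", n)
    for (i in seq_len(n)) out[[i]] <- unpack()
    out
  }
  read_map <- function(n) {
    out <- vector("list", n)
    nms <- character(n)
    for (i in seq_len(n)) {
      k <- unpack()
      if (!is.character(k)) stop("msgpack: non-string map key",
                                 call. = FALSE)
      nms[i] <- k
      out[[i]] <- unpack()
    }
    names(out) <- nms
    out
  }
  v <- unpack()
  if (pos != length(raw_bytes) + 1L)
    stop("msgpack: trailing bytes", call. = FALSE)
  v
}
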