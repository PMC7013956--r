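# Bit packing for the NUECG container. Values are packed LSB-first within
# each word and words are concatenated into a logical bit stream that
# `packBits` maps to bytes; `unpack_bits` is the exact inverse, so the
# round trip is bit-exact by construction.
pack_bits <- function(v, bits) {
  v <- as.integer(v)
  if (length(v) == 0) return(raw(0))
  if (any(v < 0) || any(v > 2^bits - 1))
    stop("values out of range for ", bits, "-bit packing", call. = FALSE)
  m <- outer(v, 0:(bits - 1), function(x, b) bitwAnd(bitwShiftR(x, b), 1L))
  bitsv <- as.logical(t(m))
  pad <- (-length(bitsv)) %% 8
  packBits(c(bitsv, rep(FALSE, pad)), type = "raw")
}

unpack_bits <- function(r, n, bits) {
  if (n == 0) return(integer(0))
  bv <- as.integer(rawToBits(r))
  if (length(bv) < n * bits)
    stop("bit stream truncated", call. = FALSE)
  m <- matrix(bv[seq_len(n * bits)], ncol = bits, byrow = TRUE)
  as.integer(m %*% 2^(0:(bits - 1)))
}

NUECG_MAGIC <- charToRaw("NUECG1")

#' Read and write the NUECG binary container
#'
#' A compact little-endian container for non-uniform ECG records. Layout:
#' a 6-byte magic `"NUECG1"`, version and flags bytes (flag bit 0 marks
#' float64 sample storage), lead count (uint16), `fs` and `fm` (float64),
#' `quant_bits` and `bit_depth` (uint8), code count and uniform sample count
#' (uint32), amplitude resolution in microvolts per LSB (float64, NaN when
#' absent), and length-prefixed lead labels. The payload is the bit-packed
#' shared code stream (`quant_bits` bits per code, padded to a byte
#' boundary), followed by the sample values: offset-binary integers packed
#' at `bit_depth` bits in lead-major order (one contiguous bit stream), or
#' raw float64 words for exact-amplitude records.
#'
#' The round trip `read_nuecg(write_nuecg(nu))` is bit-exact; truncated or
#' malformed files raise a format error.
#'
#' @param nu an `nuecg` object.
#' @param path file path.
#' @return `read_nuecg` returns an `nuecg`; `write_nuecg` returns `path`
#'   invisibly.
#' @export
write_nuecg <- function(nu, path) {
  stopifnot(inherits(nu, "nuecg"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(NUECG_MAGIC, con)
  flags <- if (nu$value_format == "float") 1L else 0L
  writeBin(as.raw(c(1L, flags)), con)                       # version, flags
  writeBin(as.integer(ncol(nu$values)), con, size = 2, endian = "little")
  writeBin(as.double(c(nu$policy$fs, nu$policy$fm)), con, endian = "little")
  writeBin(as.raw(c(nu$policy$quant_bits, nu$bit_depth)), con)
  writeBin(as.integer(c(length(nu$codes), nu$n_samples_uniform)), con,
           size = 4, endian = "little")
  writeBin(as.double(ifelse(is.finite(nu$resolution_uv),
                            nu$resolution_uv, NaN)), con, endian = "little")
  for (lab in nu$lead_labels) {
    b <- charToRaw(lab)
    writeBin(as.raw(length(b)), con)
    writeBin(b, con)
  }
  writeBin(pack_bits(nu$codes, nu$policy$quant_bits), con)
  if (nu$value_format == "int") {
    offset <- 2L^(nu$bit_depth - 1L)
    writeBin(pack_bits(as.vector(nu$values) + offset, nu$bit_depth), con)
  } else {
    writeBin(as.double(as.vector(nu$values)), con, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nuecg
#' @export
read_nuecg <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  fail <- function(why) stop("malformed NUECG file: ", why, call. = FALSE)
  need <- function(x, n) if (length(x) < n) fail("truncated") else x

  magic <- readBin(con, "raw", 6)
  if (length(magic) < 6 || !identical(magic, NUECG_MAGIC)) fail("bad magic")
  vf <- need(readBin(con, "raw", 2), 2)
  version <- as.integer(vf[1])
  if (version != 1L) fail(paste("unsupported version", version))
  is_float <- bitwAnd(as.integer(vf[2]), 1L) == 1L
  nl <- need(readBin(con, "integer", 1, size = 2, endian = "little",
                     signed = FALSE), 1)
  rates <- need(readBin(con, "double", 2, endian = "little"), 2)
  qb_bd <- need(readBin(con, "raw", 2), 2)
  counts <- need(readBin(con, "integer", 2, size = 4, endian = "little"), 2)
  res <- need(readBin(con, "double", 1, endian = "little"), 1)
  quant_bits <- as.integer(qb_bd[1])
  bit_depth <- as.integer(qb_bd[2])
  n_codes <- counts[1]
  if (nl < 1 || n_codes < 1 || rates[1] <= rates[2]) fail("bad header")
  labels <- character(nl)
  for (i in seq_len(nl)) {
    len <- as.integer(need(readBin(con, "raw", 1), 1))
    labels[i] <- rawToChar(need(readBin(con, "raw", len), len))
  }
  policy <- sampling_policy(fs = rates[1], fm = rates[2],
                            quant_bits = quant_bits)

  code_bytes <- ceiling(n_codes * quant_bits / 8)
  codes <- unpack_bits(need(readBin(con, "raw", code_bytes), code_bytes),
                       n_codes, quant_bits)
  if (is_float) {
    vals <- need(readBin(con, "double", n_codes * nl, endian = "little"),
                 n_codes * nl)
    values <- matrix(vals, n_codes, nl)
    fmt <- "float"
  } else {
    val_bytes <- ceiling(n_codes * nl * bit_depth / 8)
    raws <- need(readBin(con, "raw", val_bytes), val_bytes)
    offset <- 2L^(bit_depth - 1L)
    values <- matrix(unpack_bits(raws, n_codes * nl, bit_depth) - offset,
                     n_codes, nl)
    fmt <- "int"
  }

  structure(
    list(policy = policy, lead_labels = labels,
         bit_depth = bit_depth, value_format = fmt,
         resolution_uv = if (is.nan(res)) NA_real_ else res,
         codes = codes, values = values,
         n_samples_uniform = counts[2]),
    class = "nuecg")
}

#' Exact payload size of a non-uniform record, in bits
#'
#' Counts the side channel (`M * quant_bits`) plus the sample values
#' (`M * n_leads * bit_depth`), excluding the fixed header and any byte
#' padding; this is the quantity entering the compression ratio.
#'
#' @param nu an `nuecg` object.
#' @return Number of bits.
#' @export
nuecg_payload_bits <- function(nu) {
  stopifnot(inherits(nu, "nuecg"))
  m <- length(nu$codes)
  m * nu$policy$quant_bits + m * ncol(nu$values) * nu$bit_depth
}
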