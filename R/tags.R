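# Photon time-tag streams and the TTG1 container format.

#' Photon time-tag stream
#'
#' Ordered photon arrival timestamps for one detection channel. Timestamps
#' are integer picoseconds held as doubles (exact below 2^53 ps ~ 2.5 h).
#'
#' @param times_ps strictly increasing arrival times, ps, within
#'   `[0, duration_s * 1e12)`
#' @param channel detector id (integer)
#' @param duration_s measurement duration, s
#' @return object of class `tag_stream`; the mean count rate (Hz) is derived
#' @export
tag_stream <- function(times_ps, channel = 1L, duration_s) {
  .assert(!is.unsorted(times_ps, strictly = TRUE),
          "timestamps must be strictly increasing")
  .assert(length(times_ps) == 0 ||
            (times_ps[1] >= 0 && times_ps[length(times_ps)] < duration_s * 1e12),
          "timestamps must lie in [0, duration)")
  structure(list(times_ps = as.numeric(times_ps),
                 channel = as.integer(channel),
                 duration_s = duration_s,
                 count_rate_hz = length(times_ps) / duration_s),
            class = "tag_stream")
}

#' @export
print.tag_stream <- function(x, ...) {
  cat(sprintf("tag_stream: channel %d, %d photons in %.3g s (%.3g kHz)\n",
              x$channel, length(x$times_ps), x$duration_s,
              x$count_rate_hz / 1e3))
  invisible(x)
}

.u64_to_raw <- function(x) {
  # little-endian 8-byte encoding of a non-negative integer-valued double
  out <- raw(8 * length(x))
  for (b in 1:8) {
    out[seq(b, by = 8, length.out = length(x))] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

.raw_to_u64 <- function(r) {
  n <- length(r) / 8
  m <- matrix(as.numeric(r), nrow = 8)
  drop(2^(8 * (0:7)) %*% m)
}

#' Read / write photon tags in the TTG1 binary container
#'
#' 16-byte header (magic "TTG1", u16 version, u16 channel count, u64
#' reserved) followed by 9-byte records (u8 channel, u64 little-endian
#' picoseconds). Timestamps must be monotone per channel; the round trip is
#' bit-exact. A CSV alternative with columns `channel,time_ps` is provided
#' by [write_tags_csv()] / [read_tags_csv()].
#'
#' @param streams list of [tag_stream()] (one per channel)
#' @param path file path
#' @return `read_ttg1` returns a list of [tag_stream()]; writers return
#'   `path` invisibly
#' @export
write_ttg1 <- function(streams, path) {
  if (inherits(streams, "tag_stream")) streams <- list(streams)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TTG1"), con)
  writeBin(as.raw(c(1, 0)), con)                       # version u16 LE
  nch <- length(streams)
  writeBin(as.raw(c(nch %% 256, nch %/% 256)), con)     # channel count
  writeBin(raw(8), con)                                 # reserved
  # merge channels in time order
  ch <- unlist(lapply(streams, function(s)
    rep(s$channel, length(s$times_ps))))
  tt <- unlist(lapply(streams, function(s) s$times_ps))
  o <- order(tt, ch)
  ch <- ch[o]; tt <- tt[o]
  rec <- raw(9 * length(tt))
  idx <- seq(1, by = 9, length.out = length(tt))
  rec[idx] <- as.raw(ch)
  tr <- .u64_to_raw(tt)
  for (b in 1:8) rec[idx + b] <- tr[seq(b, by = 8, length.out = length(tt))]
  writeBin(rec, con)
  invisible(path)
}

#' @rdname write_ttg1
#' @param duration_s stream duration to record on the returned streams; when
#'   `NULL` it is taken as the last timestamp rounded up to the next second
#' @export
read_ttg1 <- function(path, duration_s = NULL) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  .assert(magic == "TTG1", "not a TTG1 file")
  ver <- .raw_to_u64(c(readBin(con, "raw", 2), raw(6)))
  .assert(ver == 1, "unsupported TTG1 version")
  nch <- .raw_to_u64(c(readBin(con, "raw", 2), raw(6)))
  readBin(con, "raw", 8)
  nrec <- (sz - 16) / 9
  .assert(nrec == floor(nrec), "truncated TTG1 record section")
  rec <- readBin(con, "raw", sz - 16)
  idx <- seq(1, by = 9, length.out = nrec)
  ch <- as.integer(rec[idx])
  tr <- raw(8 * nrec)
  for (b in 1:8) tr[seq(b, by = 8, length.out = nrec)] <- rec[idx + b]
  tt <- .raw_to_u64(tr)
  if (is.null(duration_s))
    duration_s <- if (nrec == 0) 1 else ceiling((max(tt) + 1) / 1e12)
  lapply(sort(unique(ch)), function(cc) {
    t_c <- tt[ch == cc]
    .assert(!is.unsorted(t_c, strictly = TRUE),
            sprintf("channel %d timestamps not monotone", cc))
    tag_stream(t_c, channel = cc, duration_s = duration_s)
  })
}

#' @rdname write_ttg1
#' @export
write_tags_csv <- function(streams, path) {
  if (inherits(streams, "tag_stream")) streams <- list(streams)
  ch <- unlist(lapply(streams, function(s)
    rep(s$channel, length(s$times_ps))))
  tt <- unlist(lapply(streams, function(s) s$times_ps))
  o <- order(tt, ch)
  df <- data.frame(channel = ch[o], time_ps = format(tt[o], scientific = FALSE,
                                                     trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ttg1
#' @export
read_tags_csv <- function(path, duration_s = NULL) {
  df <- read.csv(path)
  .assert(all(c("channel", "time_ps") %in% names(df)),
          "tags CSV needs channel,time_ps columns")
  tt <- as.numeric(df$time_ps)
  if (is.null(duration_s))
    duration_s <- if (nrow(df) == 0) 1 else ceiling((max(tt) + 1) / 1e12)
  lapply(sort(unique(df$channel)), function(cc) {
    t_c <- tt[df$channel == cc]
    .assert(!is.unsorted(t_c, strictly = TRUE),
            sprintf("channel %d timestamps not monotone", cc))
    tag_stream(t_c, channel = cc, duration_s = duration_s)
  })
}
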