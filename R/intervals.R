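# Half-open time intervals [start, end), represented as a data frame with
# POSIXct columns `start` and `end`, kept sorted and non-overlapping.
# All durations are in minutes.

iv_new <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(tibble(start = as.POSIXct(character(), tz = "UTC"),
                  end   = as.POSIXct(character(), tz = "UTC")))
  }
  keep <- as.numeric(end) > as.numeric(start)
  tibble(start = start[keep], end = end[keep])
}

# merge touching/overlapping intervals into a canonical disjoint set
iv_normalise <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  s <- as.numeric(iv$start); e <- as.numeric(iv$end)
  out_s <- s[1]; out_e <- e[1]
  if (nrow(iv) > 1L) {
    for (k in 2:nrow(iv)) {
      last <- length(out_e)
      if (s[k] <= out_e[last]) {
        out_e[last] <- max(out_e[last], e[k])
      } else {
        out_s <- c(out_s, s[k]); out_e <- c(out_e, e[k])
      }
    }
  }
  iv_new(as.POSIXct(out_s, origin = "1970-01-01", tz = "UTC"),
         as.POSIXct(out_e, origin = "1970-01-01", tz = "UTC"))
}

iv_intersect <- function(a, b) {
  a <- iv_normalise(a); b <- iv_normalise(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_new(a$start[0], a$end[0]))
  out_s <- numeric(0); out_e <- numeric(0)
  as_ <- as.numeric(a$start); ae <- as.numeric(a$end)
  bs <- as.numeric(b$start); be <- as.numeric(b$end)
  for (i in seq_along(as_)) {
    s <- pmax(as_[i], bs); e <- pmin(ae[i], be)
    ok <- e > s
    out_s <- c(out_s, s[ok]); out_e <- c(out_e, e[ok])
  }
  iv_normalise(iv_new(as.POSIXct(out_s, origin = "1970-01-01", tz = "UTC"),
                      as.POSIXct(out_e, origin = "1970-01-01", tz = "UTC")))
}

iv_total_minutes <- function(iv) {
  if (nrow(iv) == 0L) return(0)
  sum(as.numeric(iv$end) - as.numeric(iv$start)) / 60
}

# minutes of overlap between one epoch [start, start + minutes) and an
# interval set; vectorised over epochs
epoch_overlap_minutes <- function(epoch_start, epoch_minutes, iv) {
  iv <- iv_normalise(iv)
  out <- numeric(length(epoch_start))
  if (nrow(iv) == 0L) return(out)
  es <- as.numeric(epoch_start)
  ee <- es + epoch_minutes * 60
  for (k in seq_len(nrow(iv))) {
    s <- as.numeric(iv$start[k]); e <- as.numeric(iv$end[k])
    out <- out + pmax(0, (pmin(ee, e) - pmax(es, s))) / 60
  }
  out
}
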