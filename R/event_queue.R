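# Future-event queue for the discrete event engine: a binary min-heap keyed
# by (time, kind priority, insertion order). Implemented on growable vectors
# inside an environment so push/pop are O(log n) without copying payloads.

# Fixed tie-break priority when events share a timestamp: goods must be on
# hand before anything else fires, so arrivals precede departures, which
# precede reviews, which precede consumer arrivals.
EVENT_PRIORITY <- c(
  daily_cycle      = -2L,
  burn_in_snapshot = -1L,
  vehicle_arrival  = 1L,
  production_entry = 2L,
  vehicle_departure = 3L,
  daily_review     = 4L,
  consumer_arrival = 5L,
  export_draw      = 6L,
  expiration_sweep = 7L,
  end_of_run       = 99L
)

#' Create an empty future-event queue
#'
#' The queue is a binary min-heap ordered by event time, with ties broken by
#' a fixed kind priority (arrivals before departures before reviews before
#' consumer arrivals) and then by insertion order, so replaying the same
#' schedule always processes events identically.
#'
#' @return An `event_queue` object.
#' @seealso [schedule_event()], [next_event()]
#' @export
new_event_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$time <- numeric(0)
  q$prio <- integer(0)
  q$seq <- integer(0)
  q$payload <- list()
  q$n <- 0L
  q$counter <- 0L
  q$clock <- 0
  class(q) <- "event_queue"
  q
}

#' Schedule an event on the queue
#'
#' @param queue An [new_event_queue()].
#' @param time Event time in hours from simulation start; must not precede
#'   the queue clock (the time of the last popped event).
#' @param kind Event kind; one of `names(vegchain:::EVENT_PRIORITY)`.
#' @param payload Arbitrary kind-specific payload.
#' @return The queue, invisibly (modified in place).
#' @export
schedule_event <- function(queue, time, kind, payload = NULL) {
  if (!kind %in% names(EVENT_PRIORITY))
    stop("unknown event kind: ", kind)
  if (time < queue$clock)
    stop("cannot schedule in the past (t=", time, " < clock ", queue$clock, ")")
  i <- queue$n + 1L
  queue$counter <- queue$counter + 1L
  tm <- queue$time
  pr <- queue$prio
  sq <- queue$seq
  pl <- queue$payload
  tm[i] <- time
  pr[i] <- EVENT_PRIORITY[[kind]]
  sq[i] <- queue$counter
  pl[[i]] <- list(kind = kind, payload = payload)
  queue$n <- i
  # sift up
  while (i > 1L) {
    p <- i %/% 2L
    lt <- if (tm[i] != tm[p]) tm[i] < tm[p] else
      if (pr[i] != pr[p]) pr[i] < pr[p] else sq[i] < sq[p]
    if (!lt) break
    t1 <- tm[i]; tm[i] <- tm[p]; tm[p] <- t1
    t2 <- pr[i]; pr[i] <- pr[p]; pr[p] <- t2
    t3 <- sq[i]; sq[i] <- sq[p]; sq[p] <- t3
    t4 <- pl[[i]]; pl[i] <- pl[p]; pl[p] <- list(t4)
    i <- p
  }
  queue$time <- tm
  queue$prio <- pr
  queue$seq <- sq
  queue$payload <- pl
  invisible(queue)
}

#' Pop the next event in time order
#'
#' @param queue An [new_event_queue()].
#' @return `NULL` when the queue is empty, otherwise a list with `time`,
#'   `kind` and `payload`. Advances the queue clock to the event time.
#' @export
next_event <- function(queue) {
  n <- queue$n
  if (n == 0L) return(NULL)
  tm <- queue$time
  pr <- queue$prio
  sq <- queue$seq
  pl <- queue$payload
  out <- list(time = tm[1L], kind = pl[[1L]]$kind,
              payload = pl[[1L]]$payload)
  tm[1L] <- tm[n]; pr[1L] <- pr[n]; sq[1L] <- sq[n]
  pl[1L] <- pl[n]
  pl[n] <- list(NULL)
  n <- n - 1L
  queue$n <- n
  i <- 1L
  repeat {
    l <- 2L * i
    r <- l + 1L
    sm <- i
    if (l <= n) {
      if (if (tm[l] != tm[sm]) tm[l] < tm[sm] else
          if (pr[l] != pr[sm]) pr[l] < pr[sm] else sq[l] < sq[sm]) sm <- l
    }
    if (r <= n) {
      if (if (tm[r] != tm[sm]) tm[r] < tm[sm] else
          if (pr[r] != pr[sm]) pr[r] < pr[sm] else sq[r] < sq[sm]) sm <- r
    }
    if (sm == i) break
    t1 <- tm[i]; tm[i] <- tm[sm]; tm[sm] <- t1
    t2 <- pr[i]; pr[i] <- pr[sm]; pr[sm] <- t2
    t3 <- sq[i]; sq[i] <- sq[sm]; sq[sm] <- t3
    t4 <- pl[[i]]; pl[i] <- pl[sm]; pl[sm] <- list(t4)
    i <- sm
  }
  queue$time <- tm
  queue$prio <- pr
  queue$seq <- sq
  queue$payload <- pl
  queue$clock <- out$time
  out
}

#' @export
print.event_queue <- function(x, ...) {
  cat("<event_queue> ", x$n, " pending event(s), clock ", x$clock, " h\n",
      sep = "")
  invisible(x)
}
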