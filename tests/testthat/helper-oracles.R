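# independent oracles and fixture builders used across test files

# rotate a character vector of ring states by r positions
rotate_chars <- function(ch, r) ch[((seq_along(ch) - 1 + r) %% length(ch)) + 1]

# brute-force orbit partition of all 64 P/F strings under rotation
brute_necklace_classes <- function() {
  all_strings <- apply(expand.grid(rep(list(c("F", "P")), 6)), 1, paste,
                       collapse = "")
  canon <- vapply(all_strings, function(s) {
    ch <- strsplit(s, "")[[1]]
    min(vapply(0:5, function(r) paste(rotate_chars(ch, r), collapse = ""),
               character(1)))
  }, character(1))
  split(all_strings, canon)
}

# single-plane signed crossing count of the plane z = z0 on an unwrapped
# trajectory (columns = ions); the simple oracle for smooth drift runs
single_plane_net <- function(zu, z0) {
  sum(apply(zu, 2, function(zz) {
    side <- zz > z0
    sum(diff(side) == 1) - sum(diff(side) == -1)
  }))
}

# exhaustive in-plane grid search for the inscribed-sphere radius at height z
grid_pore_radius <- function(atoms, z, centre = c(0, 0), half_width = 3,
                             step = 0.01, cutoff = 15) {
  co <- atoms@coords
  sel <- abs(co[, 3] - z) <= cutoff
  co <- co[sel, , drop = FALSE]
  vr <- atoms@radius[sel]
  gx <- seq(centre[1] - half_width, centre[1] + half_width, by = step)
  gy <- seq(centre[2] - half_width, centre[2] + half_width, by = step)
  best <- -Inf
  best_xy <- centre
  for (yy in gy) {
    d2 <- outer(gx, co[, 1], function(a, b) (a - b)^2)
    d <- sqrt(sweep(d2, 2, (yy - co[, 2])^2 + (z - co[, 3])^2, "+"))
    clear <- apply(sweep(d, 2, vr, "-"), 1, min)
    i <- which.max(clear)
    if (clear[i] > best) {
      best <- clear[i]
      best_xy <- c(gx[i], yy)
    }
  }
  list(radius = max(best, 0), centre = best_xy)
}

# build an expanded D6 ProtomerTable (states assigned) from ring strings;
# ring1/ring2 are character vectors of length-6 P/F strings, one per particle
table_from_rings <- function(ring1, ring2) {
  stopifnot(length(ring1) == length(ring2))
  n <- length(ring1)
  st <- character(0)
  for (i in seq_len(n))
    st <- c(st, strsplit(ring1[i], "")[[1]], strsplit(ring2[i], "")[[1]])
  state <- ifelse(st == "P", "PLN", "FN")
  rec <- data.frame(
    particle_id = rep(sprintf("p%04d", seq_len(n)), each = 12L),
    class_id = ifelse(st == "P", 1L, 5L),
    state = state,
    rot_deg = rep(seq(0, 300, by = 60), 2L * n),
    tilt_flipped = rep(rep(c(FALSE, TRUE), each = 6L), n),
    stringsAsFactors = FALSE)
  rec$hemichannel_index <- as.integer(rec$tilt_flipped)
  rec$position_index <- as.integer(round(rec$rot_deg / 60) %% 6)
  ProtomerTable(rec, symmetryGroup = "D6")
}

# CompositionSet straight from single rings (C6), bypassing the table
comp_set_from_rings <- function(rings) {
  comp <- data.frame(
    particle_id = sprintf("r%06d", seq_along(rings)),
    n_PLN = nchar(gsub("[^P]", "", rings)),
    n_FN = nchar(gsub("[^F]", "", rings)),
    n_OTHER = 0L, n_UNASSIGNED = 0L,
    ring1 = rings, ring2 = NA_character_,
    stringsAsFactors = FALSE)
  comp$k_PLN <- comp$n_PLN
  new("CompositionSet", compositions = comp, symmetryGroup = "C6",
      nDuplicatesRemoved = 0L, incompleteParticles = character())
}

# fast iid ring generator: n length-6 P/F strings at PLN probability p
random_rings <- function(n, p) {
  m <- matrix(ifelse(matrix(rbinom(6 * n, 1, p), n) == 1, "P", "F"), n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# hand-built IonTrajectory around a given z path (single ion unless z is a
# matrix), x = y = 0
traj_from_z <- function(z, dt = 1, box = c(40, 40, 100), voltage = 0,
                        species = "NA", charge = 1) {
  z <- as.matrix(z)
  zero <- matrix(0, nrow(z), ncol(z))
  IonTrajectory(zero, zero, z, species = rep(species, ncol(z)),
                charge = rep(charge, ncol(z)), dt = dt, box = box,
                voltage = voltage)
}
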