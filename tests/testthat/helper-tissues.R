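# Small tissues built in code for the unit tests.

# A single square cell of side `s`, bordered by medium, with 4 junction
# nodes (corner junctions are 2-valent, as for any isolated cell).
square_tissue <- function(s = 1, tension = 1) {
  pos <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  edges <- list(
    list(chain = c(1L, 2L), rl = 1L, rr = 0L, tension = tension),
    list(chain = c(2L, 3L), rl = 1L, rr = 0L, tension = tension),
    list(chain = c(3L, 4L), rl = 1L, rr = 0L, tension = tension),
    list(chain = c(4L, 1L), rl = 1L, rr = 0L, tension = tension))
  cells <- list(list(type = "cell", target_area = s^2, mu = 1))
  new_tissue(pos, rep(1L, 4L), edges, cells)
}

# An arbitrary simple polygon as one cell (CCW vertex matrix).
polygon_tissue <- function(xy, tension = 1) {
  n <- nrow(xy)
  edges <- lapply(seq_len(n), function(i)
    list(chain = c(i, if (i == n) 1L else i + 1L), rl = 1L, rr = 0L,
         tension = tension))
  cells <- list(list(type = "cell", target_area = NA_real_, mu = 1))
  new_tissue(xy, rep(1L, n), edges, cells)
}

# Two abutting unit squares sharing a vertical edge: cells 1 (left, type a)
# and 2 (right, type b).
doublet_square_tissue <- function(ta = 1, tb = 1, tab = 1) {
  pos <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(2, 0), c(2, 1))
  edges <- list(
    list(chain = c(1L, 2L), rl = 1L, rr = 0L, tension = ta),
    list(chain = c(2L, 3L), rl = 1L, rr = 2L, tension = tab),  # shared
    list(chain = c(3L, 4L), rl = 1L, rr = 0L, tension = ta),
    list(chain = c(4L, 1L), rl = 1L, rr = 0L, tension = ta),
    list(chain = c(2L, 5L), rl = 2L, rr = 0L, tension = tb),
    list(chain = c(5L, 6L), rl = 2L, rr = 0L, tension = tb),
    list(chain = c(6L, 3L), rl = 2L, rr = 0L, tension = tb))
  cells <- list(list(type = "a", target_area = 1, mu = 1),
                list(type = "b", target_area = 1, mu = 1))
  new_tissue(pos, rep(1L, 6L), edges, cells)
}

# 2x2 block of unit squares ("quartet") with a short central edge created
# by pinching the two central junctions together; the four cells meet the
# centre two-by-two: cells 1 (SW), 2 (SE), 3 (NE), 4 (NW).  Cells 1 and 3
# share the short central edge; 2 and 4 do not touch.
quartet_tissue <- function(eps = 0.1, tension = 1) {
  # outer 3x3 lattice of corner nodes minus centre, plus two centre nodes
  pos <- rbind(
    c(0, 0), c(1, 0), c(2, 0),          # 1 2 3  bottom
    c(0, 1), c(2, 1),                   # 4 5    middle sides
    c(0, 2), c(1, 2), c(2, 2),          # 6 7 8  top
    c(1, 1 - eps / 2), c(1, 1 + eps / 2))  # 9 10  pinched centre pair
  edges <- list(
    list(chain = c(1L, 2L), rl = 1L, rr = 0L, tension = tension),   # 1
    list(chain = c(2L, 3L), rl = 2L, rr = 0L, tension = tension),   # 2
    list(chain = c(3L, 5L), rl = 2L, rr = 0L, tension = tension),   # 3
    list(chain = c(5L, 8L), rl = 3L, rr = 0L, tension = tension),   # 4
    list(chain = c(8L, 7L), rl = 3L, rr = 0L, tension = tension),   # 5
    list(chain = c(7L, 6L), rl = 4L, rr = 0L, tension = tension),   # 6
    list(chain = c(6L, 4L), rl = 4L, rr = 0L, tension = tension),   # 7
    list(chain = c(4L, 1L), rl = 1L, rr = 0L, tension = tension),   # 8
    list(chain = c(2L, 9L), rl = 1L, rr = 2L, tension = tension),   # 9 south spoke
    list(chain = c(9L, 10L), rl = 1L, rr = 3L, tension = tension),  # 10 centre
    list(chain = c(10L, 7L), rl = 4L, rr = 3L, tension = tension),  # 11 north spoke
    list(chain = c(9L, 5L), rl = 3L, rr = 2L, tension = tension),   # 12 east spoke
    list(chain = c(4L, 10L), rl = 4L, rr = 1L, tension = tension))  # 13 west spoke
  cells <- list(
    list(type = "cell", target_area = NA_real_, mu = 1),
    list(type = "cell", target_area = NA_real_, mu = 1),
    list(type = "cell", target_area = NA_real_, mu = 1),
    list(type = "cell", target_area = NA_real_, mu = 1))
  new_tissue(pos, rep(1L, 10L), edges, cells)
}

# Uniform tension table for one-type tissues.
uniform_tensions <- function(gamma = 1)
  tension_table("cell|cell" = gamma, "cell|medium" = gamma)

# A relaxed single polyline cell: regular n-gon of given area refined into
# many segments (used for Laplace-law style checks).
ngon_cell <- function(n = 24L, area = pi / 4, tension = 1) {
  R <- sqrt(2 * area / (n * sin(2 * pi / n)))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  polygon_tissue(cbind(R * cos(th), R * sin(th)), tension = tension)
}
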