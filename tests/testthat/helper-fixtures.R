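# Shared fixtures, all built in code at test time.

# small deterministic record set drawn around plum-like dimensions
make_records <- function(n, seed = 1, noise_sd = 0, gen_a = 0, gen_b = 0.0225,
                         form = "LD") {
  withr::with_seed(seed, {
    L <- runif(n, 21, 32)
    D <- runif(n, 19, 30)
    f <- form_basis(form)
    data.frame(length_mm = L, diameter_mm = D,
               weight_g = gen_a + gen_b * f(L, D) + rnorm(n, 0, noise_sd))
  })
}

# axis-aligned (or rotated) solid ellipse mask on an h x w frame
ellipse_mask <- function(h, w, a, b, theta_deg = 0, cx = w / 2, cy = h / 2) {
  th <- theta_deg * pi / 180
  x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w) - cx
  y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w) - cy
  u <- (x * cos(th) + y * sin(th)) / a
  v <- (-x * sin(th) + y * cos(th)) / b
  u^2 + v^2 <= 1
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# distinct 8-connected foreground components of a mask
count_components <- function(mask) {
  lab <- plumfw:::.cpp_label_components(mask, 8L)
  unique(lab[lab > 0])
}

# dense QP oracle for the epsilon-SVR dual: scipy SLSQP via the python
# interpreter shipped in the runtime image (multi-start, tight ftol)
svr_qp_oracle_objective <- function(K, y, C, eps) {
  inp <- tempfile(fileext = ".json")
  on.exit(unlink(inp))
  jsonlite::write_json(list(K = K, y = y, C = C, eps = eps), inp,
                       digits = NA, matrix = "rowmajor")
  script <- '
import json, sys, numpy as np
from scipy.optimize import minimize
d = json.load(open(sys.argv[1]))
K = np.array(d["K"]); y = np.array(d["y"])
C = d["C"][0]; eps = d["eps"][0]
n = len(y)
def obj(x):
    b = x[:n] - x[n:]
    return 0.5 * b @ K @ b + eps * x.sum() - y @ b
def grad(x):
    b = x[:n] - x[n:]
    Kb = K @ b
    return np.concatenate([Kb + eps - y, -Kb + eps + y])
cons = [{"type": "eq", "fun": lambda x: x[:n].sum() - x[n:].sum(),
         "jac": lambda x: np.concatenate([np.ones(n), -np.ones(n)])}]
best = None
for s in range(3):
    rng = np.random.default_rng(s)
    x0 = rng.uniform(0, min(C, 1.0), 2 * n)
    r = minimize(obj, x0, jac=grad, bounds=[(0, C)] * (2 * n),
                 constraints=cons, method="SLSQP",
                 options={"maxiter": 2000, "ftol": 1e-14})
    if r.success and (best is None or r.fun < best):
        best = r.fun
print(f"{best:.16g}")
'
  out <- system2("python", c("-c", shQuote(script), inp), stdout = TRUE)
  as.numeric(out[length(out)])
}
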