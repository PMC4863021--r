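# Independent reference implementation (run from the repository root:
#   python tools/oracle_spei.py) of the SPEI (log-logistic / unbiased
# PWM) and SPI (gamma ML + zero point mass) standardization recipes, used
# once to generate frozen text fixtures for the R package's tests.
# Entirely separate code path: numpy/scipy only.
import numpy as np
from scipy.stats import norm, gamma as gamma_dist
from scipy.optimize import brentq
from scipy.special import gamma as gfun, digamma

rng = np.random.RandomState(20240)
YEARS = 50
N = YEARS * 12
month = np.tile(np.arange(1, 13), YEARS)

# synthetic water-balance series: seasonal cycle + skewed noise
seas = 30 * np.sin((month - 4) * 2 * np.pi / 12)
d = seas + rng.gamma(2.0, 25.0, N) - 50 + rng.normal(0, 10, N)

# synthetic precipitation with occasional exact zeros in dry months
pmean = np.array([12, 11, 22, 35, 55, 85, 70, 60, 45, 30, 18, 13])
precip = rng.gamma(2.0, pmean[month - 1] / 2.0, N)
zero_p = np.array([0.08, 0.08, 0.04, 0.0, 0, 0, 0, 0, 0, 0.0, 0.04, 0.08])
precip[rng.uniform(size=N) < zero_p[month - 1]] = 0.0

# freeze the exact inputs the fixture stores
d = np.round(d, 4)
precip = np.round(precip, 4)


def agg(x, k):
    out = np.full(len(x), np.nan)
    for m in range(k - 1, len(x)):
        out[m] = np.sum(x[m - k + 1:m + 1])
    return out


def pwm(x):
    x = np.sort(x)
    n = len(x)
    i = np.arange(1, n + 1)
    w0 = x.mean()
    w1 = np.sum((n - i) / (n - 1) * x) / n
    w2 = np.sum((n - i) * (n - i - 1) / ((n - 1) * (n - 2)) * x) / n
    return w0, w1, w2


def spei_col(x, k):
    a = agg(x, k)
    z = np.full(len(a), np.nan)
    for mo in range(1, 13):
        sel = (month == mo) & ~np.isnan(a)
        v = a[sel]
        w0, w1, w2 = pwm(v)
        beta = (2 * w1 - w0) / (6 * w1 - w0 - 6 * w2)
        g1 = gfun(1 + 1 / beta) * gfun(1 - 1 / beta)
        alpha = (w0 - 2 * w1) * beta / g1
        gam0 = w0 - alpha * g1
        u = v - gam0
        if beta > 0:
            F = np.where(u > 0, 1 / (1 + (alpha / u) ** beta), 0.0)
        else:
            F = np.where(u < 0, 1 / (1 + (alpha / u) ** beta), 1.0)
        z[sel] = np.clip(norm.ppf(F), -6, 6)
    return z


def gamma_ml(x):
    m = x.mean()
    s = np.log(m) - np.mean(np.log(x))
    f = lambda a: np.log(a) - digamma(a) - s
    a0 = (1 + np.sqrt(1 + 4 * s / 3)) / (4 * s)
    shape = brentq(f, a0 / 100, a0 * 100)
    return shape, shape / m  # shape, rate


def spi_col(x, k):
    a = agg(x, k)
    z = np.full(len(a), np.nan)
    for mo in range(1, 13):
        sel = (month == mo) & ~np.isnan(a)
        v = a[sel]
        pos = v[v > 0]
        q = (len(v) - len(pos)) / len(v)
        shape, rate = gamma_ml(pos)
        H = q + (1 - q) * gamma_dist.cdf(v, shape, scale=1 / rate)
        H[v == 0] = q
        z[sel] = np.clip(norm.ppf(H), -6, 6)
    return z


cols = {
    "month": month,
    "d": d,
    "precip": precip,
    "spei_k3": np.round(spei_col(d, 3), 6),
    "spei_k12": np.round(spei_col(d, 12), 6),
    "spi_k1": np.round(spi_col(precip, 1), 6),
    "spi_k2": np.round(spi_col(precip, 2), 6),
    "spi_k3": np.round(spi_col(precip, 3), 6),
}

out = "tests/testthat/fixture-spei-oracle-synthetic.csv"
with open(out, "w") as fh:
    fh.write(",".join(cols.keys()) + "\n")
    for r in range(N):
        fh.write(",".join("NA" if isinstance(v[r], float) and np.isnan(v[r])
                          else str(v[r]) for v in cols.values()) + "\n")
print("wrote", out)
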