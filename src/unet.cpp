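// Compact encoder-decoder ("hourglass") segmentation network with a joint
// eye/blink classification branch, implemented directly on Armadillo
// matrices. Feature maps are stored as (H*W) x C matrices in R's
// column-major pixel order (pixel p = y + x*H), so im2col reduces every
// 3x3 "same" convolution to a single BLAS gemm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct ConvP {
  arma::fmat W;    // (9*Cin) x Cout, or Cin x Cout for the 1x1 head
  arma::frowvec b; // Cout
};

struct Net {
  int depth, k, width, cin;
  std::vector<std::vector<ConvP> > enc; // [depth][k]
  std::vector<std::vector<ConvP> > dec; // [depth-1][k], index l-1 for level l
  ConvP head;                           // 1x1 conv, width -> 1
  arma::fmat fcW;                        // width x 2 (eye, blink)
  arma::frowvec fcb;                     // 2
};

static ConvP get_conv(const List& params, const std::string& key) {
  ConvP c;
  c.W = as<arma::fmat>(params[key + ".W"]);
  c.b = arma::frowvec(as<arma::fvec>(params[key + ".b"]).t());
  return c;
}

static Net load_net(const List& params, const List& cfg) {
  Net n;
  n.depth = as<int>(cfg["depth"]);
  n.k = as<int>(cfg["convs_per_level"]);
  n.width = as<int>(cfg["width"]);
  n.cin = as<int>(cfg["channels_in"]);
  n.enc.resize(n.depth);
  for (int l = 0; l < n.depth; ++l)
    for (int j = 0; j < n.k; ++j)
      n.enc[l].push_back(get_conv(params,
        "enc" + std::to_string(l + 1) + "_" + std::to_string(j + 1)));
  n.dec.resize(n.depth - 1);
  for (int l = 0; l < n.depth - 1; ++l)
    for (int j = 0; j < n.k; ++j)
      n.dec[l].push_back(get_conv(params,
        "dec" + std::to_string(l + 1) + "_" + std::to_string(j + 1)));
  n.head = get_conv(params, "head");
  n.fcW = as<arma::fmat>(params["fc.W"]);
  n.fcb = arma::frowvec(as<arma::fvec>(params["fc.b"]).t());
  return n;
}

// 3x3 patch matrix with zero padding; column k = c*9 + (dx+1)*3 + (dy+1)
static arma::fmat im2col3(const arma::fmat& X, int H, int W) {
  const int C = X.n_cols;
  arma::fmat P(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        const int k = c * 9 + (dx + 1) * 3 + (dy + 1);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int x = 0; x < W; ++x) {
          const int xs = x + dx;
          if (xs < 0 || xs >= W) continue;
          P.col(k).subvec(x * H + y0, x * H + y1 - 1) =
            X.col(c).subvec(xs * H + y0 + dy, xs * H + y1 - 1 + dy);
        }
      }
  return P;
}

// adjoint of im2col3: scatter-add patch gradients back onto the input grid
static arma::fmat col2im3(const arma::fmat& dP, int H, int W, int C) {
  arma::fmat dX(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        const int k = c * 9 + (dx + 1) * 3 + (dy + 1);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int x = 0; x < W; ++x) {
          const int xs = x + dx;
          if (xs < 0 || xs >= W) continue;
          dX.col(c).subvec(xs * H + y0 + dy, xs * H + y1 - 1 + dy) +=
            dP.col(k).subvec(x * H + y0, x * H + y1 - 1);
        }
      }
  return dX;
}

static arma::fmat conv3_fwd(const arma::fmat& X, int H, int W, const ConvP& c,
                           bool relu) {
  arma::fmat Y = im2col3(X, H, W) * c.W;
  Y.each_row() += c.b;
  if (relu) Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return Y;
}

// backward through conv3+ReLU; dY is modified in place by the ReLU mask
static arma::fmat conv3_bwd(const arma::fmat& Xin, const arma::fmat& Yout,
                           arma::fmat& dY, int H, int W, const ConvP& c,
                           bool relu, arma::fmat& gW, arma::frowvec& gb) {
  if (relu) dY %= arma::conv_to<arma::fmat>::from(Yout > 0.0);
  arma::fmat P = im2col3(Xin, H, W);
  gW += P.t() * dY;
  gb += arma::sum(dY, 0);
  arma::fmat dP = dY * c.W.t();
  return col2im3(dP, H, W, Xin.n_cols);
}

static arma::fmat maxpool2(const arma::fmat& X, int H, int W, arma::umat& idx) {
  const int C = X.n_cols, Ho = H / 2, Wo = W / 2;
  arma::fmat Y(Ho * Wo, C);
  idx.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const float* xc = X.colptr(c);
    for (int xo = 0; xo < Wo; ++xo)
      for (int yo = 0; yo < Ho; ++yo) {
        int best = -1;
        double bv = -std::numeric_limits<double>::infinity();
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            const int p = (2 * yo + i) + (2 * xo + j) * H;
            if (xc[p] > bv) { bv = xc[p]; best = p; }
          }
        Y(yo + xo * Ho, c) = bv;
        idx(yo + xo * Ho, c) = (arma::uword)best;
      }
  }
  return Y;
}

static arma::fmat maxpool2_bwd(const arma::fmat& dY, const arma::umat& idx,
                              int H, int W) {
  const int C = dY.n_cols;
  arma::fmat dX(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (arma::uword p = 0; p < dY.n_rows; ++p)
      dX(idx(p, c), c) += dY(p, c);
  return dX;
}

// parameter-free nearest-neighbour x2 upsampling (H,W = input grid)
static arma::fmat upsample2(const arma::fmat& X, int H, int W) {
  const int C = X.n_cols, Ho = 2 * H, Wo = 2 * W;
  arma::fmat Y(Ho * Wo, C);
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < Wo; ++xo) {
      const int xs = xo / 2;
      for (int yo = 0; yo < Ho; ++yo)
        Y(yo + xo * Ho, c) = X(yo / 2 + xs * H, c);
    }
  return Y;
}

static arma::fmat upsample2_bwd(const arma::fmat& dY, int H, int W) {
  // H,W = small (input) grid; dY lives on the 2H x 2W grid
  const int C = dY.n_cols, Ho = 2 * H;
  arma::fmat dX(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < 2 * W; ++xo) {
      const int xs = xo / 2;
      for (int yo = 0; yo < Ho; ++yo)
        dX(yo / 2 + xs * H, c) += dY(yo + xo * Ho, c);
    }
  return dX;
}

static double sigmoid1(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// numerically stable BCE from the logit: max(z,0) - z*y + log1p(exp(-|z|))
static double bce_logit(double z, double y) {
  return std::max(z, 0.0) - z * y + std::log1p(std::exp(-std::fabs(z)));
}

struct Cache {
  std::vector<std::vector<arma::fmat> > enc_in, enc_out;
  std::vector<arma::fmat> skip;       // per level, post-conv pre-pool output
  std::vector<arma::umat> pool_idx;
  std::vector<std::vector<arma::fmat> > dec_in, dec_out;
  arma::fmat head_in, map_logit;
  arma::fvec g, cls_logit;
};

static void forward(const Net& n, const arma::fmat& x, int H, Cache& cc) {
  cc.enc_in.assign(n.depth, std::vector<arma::fmat>());
  cc.enc_out.assign(n.depth, std::vector<arma::fmat>());
  cc.skip.assign(n.depth, arma::fmat());
  cc.pool_idx.assign(n.depth - 1, arma::umat());
  cc.dec_in.assign(n.depth - 1, std::vector<arma::fmat>());
  cc.dec_out.assign(n.depth - 1, std::vector<arma::fmat>());

  arma::fmat cur = x;
  int h = H;
  for (int l = 0; l < n.depth; ++l) {
    for (int j = 0; j < n.k; ++j) {
      cc.enc_in[l].push_back(cur);
      cur = conv3_fwd(cur, h, h, n.enc[l][j], true);
      cc.enc_out[l].push_back(cur);
    }
    cc.skip[l] = cur;
    if (l < n.depth - 1) {
      cur = maxpool2(cur, h, h, cc.pool_idx[l]);
      h /= 2;
    }
  }
  // classification branch: GAP over the bottleneck map, then FC width -> 2
  cc.g = arma::mean(cur, 0).t();
  cc.cls_logit = n.fcW.t() * cc.g + n.fcb.t();

  for (int l = n.depth - 2; l >= 0; --l) {
    arma::fmat up = upsample2(cur, h, h);
    h *= 2;
    cur = arma::join_rows(up, cc.skip[l]);
    for (int j = 0; j < n.k; ++j) {
      cc.dec_in[l].push_back(cur);
      cur = conv3_fwd(cur, h, h, n.dec[l][j], true);
      cc.dec_out[l].push_back(cur);
    }
  }
  cc.head_in = cur;
  cc.map_logit = cur * n.head.W;
  cc.map_logit.each_row() += n.head.b;
}

struct Grads {
  std::vector<std::vector<arma::fmat> > encW, decW;
  std::vector<std::vector<arma::frowvec> > encb, decb;
  arma::fmat headW, fcW;
  arma::frowvec headb, fcb;
};

static void init_grads(const Net& n, Grads& g) {
  g.encW.assign(n.depth, std::vector<arma::fmat>());
  g.encb.assign(n.depth, std::vector<arma::frowvec>());
  for (int l = 0; l < n.depth; ++l)
    for (int j = 0; j < n.k; ++j) {
      g.encW[l].push_back(arma::fmat(arma::size(n.enc[l][j].W), arma::fill::zeros));
      g.encb[l].push_back(arma::frowvec(arma::size(n.enc[l][j].b), arma::fill::zeros));
    }
  g.decW.assign(n.depth - 1, std::vector<arma::fmat>());
  g.decb.assign(n.depth - 1, std::vector<arma::frowvec>());
  for (int l = 0; l < n.depth - 1; ++l)
    for (int j = 0; j < n.k; ++j) {
      g.decW[l].push_back(arma::fmat(arma::size(n.dec[l][j].W), arma::fill::zeros));
      g.decb[l].push_back(arma::frowvec(arma::size(n.dec[l][j].b), arma::fill::zeros));
    }
  g.headW = arma::fmat(arma::size(n.head.W), arma::fill::zeros);
  g.headb = arma::frowvec(arma::size(n.head.b), arma::fill::zeros);
  g.fcW = arma::fmat(arma::size(n.fcW), arma::fill::zeros);
  g.fcb = arma::frowvec(2, arma::fill::zeros);
}

// backward pass for one sample; returns the sample's total loss
static double backward(const Net& n, const Cache& cc, int H,
                       const arma::fvec& mask, double eye, double blink,
                       Grads& g) {
  const int Npix = H * H;
  // loss
  double loss = 0.0;
  for (int p = 0; p < Npix; ++p)
    loss += bce_logit(cc.map_logit(p, 0), mask(p));
  loss /= Npix;
  loss += bce_logit(cc.cls_logit(0), eye);
  loss += bce_logit(cc.cls_logit(1), blink);

  // head gradient: d(mean pixel BCE)/dz = (sigmoid(z) - y)/Npix
  arma::fmat dmap(Npix, 1);
  for (int p = 0; p < Npix; ++p)
    dmap(p, 0) = (sigmoid1(cc.map_logit(p, 0)) - mask(p)) / Npix;
  g.headW += cc.head_in.t() * dmap;
  g.headb(0) += arma::accu(dmap);
  arma::fmat dcur = dmap * n.head.W.t();

  // decoder backward, full resolution up to the bottleneck
  std::vector<arma::fmat> dskip(n.depth);
  int h = H;
  for (int l = 0; l <= n.depth - 2; ++l) {
    for (int j = n.k - 1; j >= 0; --j)
      dcur = conv3_bwd(cc.dec_in[l][j], cc.dec_out[l][j], dcur, h, h,
                       n.dec[l][j], true, g.decW[l][j], g.decb[l][j]);
    arma::fmat dup = dcur.cols(0, n.width - 1);
    dskip[l] = dcur.cols(n.width, 2 * n.width - 1);
    h /= 2;
    dcur = upsample2_bwd(dup, h, h);
  }

  // classification branch joins at the bottleneck output
  arma::fvec dcls(2);
  dcls(0) = sigmoid1(cc.cls_logit(0)) - eye;
  dcls(1) = sigmoid1(cc.cls_logit(1)) - blink;
  g.fcW += cc.g * dcls.t();
  g.fcb += dcls.t();
  const int npix_b = h * h;
  arma::frowvec dg = (n.fcW * dcls).t() / npix_b;
  dcur.each_row() += dg;

  // encoder backward
  for (int l = n.depth - 1; l >= 0; --l) {
    arma::fmat dout;
    if (l == n.depth - 1) {
      dout = dcur;
    } else {
      dout = maxpool2_bwd(dcur, cc.pool_idx[l], 2 * h, 2 * h);
      h *= 2;
      dout += dskip[l];
    }
    arma::fmat d = dout;
    for (int j = n.k - 1; j >= 0; --j)
      d = conv3_bwd(cc.enc_in[l][j], cc.enc_out[l][j], d, h, h,
                    n.enc[l][j], true, g.encW[l][j], g.encb[l][j]);
    dcur = d;
  }
  return loss;
}

// [[Rcpp::export]]
List unet_batch_grad_cpp(List params, List cfg, arma::fcube images,
                         arma::fcube masks, arma::fvec eye, arma::fvec blink) {
  Net n = load_net(params, cfg);
  const int H = images.n_rows, B = images.n_slices;
  if ((int)images.n_cols != H) stop("images must be square");
  Grads g;
  init_grads(n, g);
  double loss = 0.0;
  Cache cc;
  for (int b = 0; b < B; ++b) {
    arma::fmat x(images.slice(b).memptr(), H * H, 1);
    arma::fvec m(masks.slice(b).memptr(), H * H);
    forward(n, x, H, cc);
    loss += backward(n, cc, H, m, eye(b), blink(b), g);
  }
  loss /= B;
  List out;
  for (int l = 0; l < n.depth; ++l)
    for (int j = 0; j < n.k; ++j) {
      std::string key = "enc" + std::to_string(l + 1) + "_" + std::to_string(j + 1);
      out[key + ".W"] = arma::conv_to<arma::mat>::from(g.encW[l][j]) / B;
      out[key + ".b"] = arma::conv_to<arma::vec>::from(g.encb[l][j]) / B;
    }
  for (int l = 0; l < n.depth - 1; ++l)
    for (int j = 0; j < n.k; ++j) {
      std::string key = "dec" + std::to_string(l + 1) + "_" + std::to_string(j + 1);
      out[key + ".W"] = arma::conv_to<arma::mat>::from(g.decW[l][j]) / B;
      out[key + ".b"] = arma::conv_to<arma::vec>::from(g.decb[l][j]) / B;
    }
  out["head.W"] = arma::conv_to<arma::mat>::from(g.headW) / B;
  out["head.b"] = arma::conv_to<arma::vec>::from(g.headb) / B;
  out["fc.W"] = arma::conv_to<arma::mat>::from(g.fcW) / B;
  out["fc.b"] = arma::conv_to<arma::vec>::from(g.fcb) / B;
  return List::create(_["loss"] = loss, _["grads"] = out);
}

// [[Rcpp::export]]
List unet_predict_cpp(List params, List cfg, arma::fcube images) {
  Net n = load_net(params, cfg);
  const int H = images.n_rows, B = images.n_slices;
  if ((int)images.n_cols != H) stop("images must be square");
  arma::fcube maps(H, H, B);
  arma::fvec eyep(B), blinkp(B);
  Cache cc;
  for (int b = 0; b < B; ++b) {
    arma::fmat x(images.slice(b).memptr(), H * H, 1);
    forward(n, x, H, cc);
    arma::fmat pm = cc.map_logit;
    pm.transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
    maps.slice(b) = arma::reshape(pm, H, H);
    eyep(b) = sigmoid1(cc.cls_logit(0));
    blinkp(b) = sigmoid1(cc.cls_logit(1));
  }
  return List::create(_["maps"] = arma::conv_to<arma::cube>::from(maps),
                      _["eye"] = arma::conv_to<arma::vec>::from(eyep),
                      _["blink"] = arma::conv_to<arma::vec>::from(blinkp));
}

// ---- binary morphology on 0/1 matrices -------------------------------------

// erosion then dilation with the 3x3 cross ("plus") structuring element
// [[Rcpp::export]]
arma::mat morph_open_cross_cpp(arma::mat mask) {
  const int H = mask.n_rows, W = mask.n_cols;
  arma::mat er(H, W, arma::fill::zeros), out(H, W, arma::fill::zeros);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (mask(y, x) == 0) continue;
      bool keep = true;
      if (y > 0 && mask(y - 1, x) == 0) keep = false;
      if (keep && y < H - 1 && mask(y + 1, x) == 0) keep = false;
      if (keep && x > 0 && mask(y, x - 1) == 0) keep = false;
      if (keep && x < W - 1 && mask(y, x + 1) == 0) keep = false;
      // border pixels: structuring element clipped to the image (no pad)
      if (keep) er(y, x) = 1;
    }
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (er(y, x) == 0) continue;
      out(y, x) = 1;
      if (y > 0) out(y - 1, x) = 1;
      if (y < H - 1) out(y + 1, x) = 1;
      if (x > 0) out(y, x - 1) = 1;
      if (x < W - 1) out(y, x + 1) = 1;
    }
  return out;
}

// keep only the largest 8-connected foreground component (ties: first found
// in column-major scan order); empty input -> empty output
// [[Rcpp::export]]
arma::mat largest_component_cpp(arma::mat mask) {
  const int H = mask.n_rows, W = mask.n_cols;
  arma::imat lab(H, W, arma::fill::zeros);
  int nlab = 0;
  std::vector<int> sizes(1, 0);
  std::vector<int> stack;
  for (int x0 = 0; x0 < W; ++x0)
    for (int y0 = 0; y0 < H; ++y0) {
      if (mask(y0, x0) == 0 || lab(y0, x0) != 0) continue;
      ++nlab;
      sizes.push_back(0);
      stack.clear();
      stack.push_back(y0 + x0 * H);
      lab(y0, x0) = nlab;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int y = p % H, x = p / H;
        ++sizes[nlab];
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (dx == 0 && dy == 0) continue;
            const int yn = y + dy, xn = x + dx;
            if (yn < 0 || yn >= H || xn < 0 || xn >= W) continue;
            if (mask(yn, xn) != 0 && lab(yn, xn) == 0) {
              lab(yn, xn) = nlab;
              stack.push_back(yn + xn * H);
            }
          }
      }
    }
  if (nlab == 0) return arma::mat(H, W, arma::fill::zeros);
  int best = 1;
  for (int i = 2; i <= nlab; ++i)
    if (sizes[i] > sizes[best]) best = i;
  arma::mat out(H, W, arma::fill::zeros);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (lab(y, x) == best) out(y, x) = 1;
  return out;
}
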