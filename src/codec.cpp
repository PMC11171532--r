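// Minimal writers/readers for the two outputs the installed packages cannot
// produce: 16-bit grayscale PNG (png::writePNG is 8-bit only) and
// uncompressed multi-channel 32-bit float TIFF for displacement fields
// (tiff::writeTIFF stores 32-bit as scaled integers). zlib supplies deflate
// and CRC32 for the PNG path.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
using namespace Rcpp;

static void put_u32be(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff); v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);  v.push_back(x & 0xff);
}

static void png_chunk(FILE* f, const char type[4],
                      const unsigned char* data, uint32_t n) {
  unsigned char len[4] = {(unsigned char)((n >> 24) & 0xff),
                          (unsigned char)((n >> 16) & 0xff),
                          (unsigned char)((n >> 8) & 0xff),
                          (unsigned char)(n & 0xff)};
  fwrite(len, 1, 4, f);
  fwrite(type, 1, 4, f);
  if (n) fwrite(data, 1, n, f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (n) crc = crc32(crc, data, n);
  unsigned char c[4] = {(unsigned char)((crc >> 24) & 0xff),
                        (unsigned char)((crc >> 16) & 0xff),
                        (unsigned char)((crc >> 8) & 0xff),
                        (unsigned char)(crc & 0xff)};
  fwrite(c, 1, 4, f);
}

// img: values already quantized to integers 0..65535 (passed as doubles).
// [[Rcpp::export]]
void cpp_write_png16(NumericMatrix img, std::string path) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<unsigned char> raw((size_t)H * (1 + (size_t)W * 2));
  size_t k = 0;
  for (int i = 0; i < H; i++) {
    raw[k++] = 0;  // filter: none
    for (int j = 0; j < W; j++) {
      const double v = img(i, j);
      if (!(v >= 0 && v <= 65535))
        stop("pixel value outside [0, 65535] at (%d, %d)", i + 1, j + 1);
      const uint16_t q = (uint16_t)(v + 0.5);
      raw[k++] = (q >> 8) & 0xff;
      raw[k++] = q & 0xff;
    }
  }
  uLongf zcap = compressBound(raw.size());
  std::vector<unsigned char> z(zcap);
  if (compress2(z.data(), &zcap, raw.data(), raw.size(), 6) != Z_OK)
    stop("PNG deflate failed");
  FILE* f = fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32be(ihdr, (uint32_t)W);
  put_u32be(ihdr, (uint32_t)H);
  ihdr.push_back(16);  // bit depth
  ihdr.push_back(0);   // grayscale
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  png_chunk(f, "IHDR", ihdr.data(), ihdr.size());
  png_chunk(f, "IDAT", z.data(), (uint32_t)zcap);
  png_chunk(f, "IEND", nullptr, 0);
  fclose(f);
}

static void put_u16le(std::vector<unsigned char>& v, uint16_t x) {
  v.push_back(x & 0xff); v.push_back((x >> 8) & 0xff);
}
static void put_u32le(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back(x & 0xff); v.push_back((x >> 8) & 0xff);
  v.push_back((x >> 16) & 0xff); v.push_back((x >> 24) & 0xff);
}
static void tag(std::vector<unsigned char>& v, uint16_t id, uint16_t type,
                uint32_t count, uint32_t value) {
  put_u16le(v, id); put_u16le(v, type); put_u32le(v, count); put_u32le(v, value);
}

// arr: H x W x C array (C interleaved samples per pixel), little-endian
// uncompressed float32, single strip.
// [[Rcpp::export]]
void cpp_write_tiff_float(NumericVector arr, int H, int W, int C,
                          std::string path) {
  const size_t npix = (size_t)H * W;
  if ((size_t)arr.size() != npix * C) stop("array size mismatch");
  const int ntags = 12;
  const uint32_t ifd_off = 8;
  const uint32_t ifd_size = 2 + ntags * 12 + 4;
  uint32_t aux_off = ifd_off + ifd_size;
  // auxiliary arrays needed when C > 1 (BitsPerSample, SampleFormat)
  uint32_t bps_off = aux_off, sf_off = aux_off;
  uint32_t data_off = aux_off;
  if (C > 1) {
    bps_off = aux_off;
    sf_off = bps_off + 2u * C;
    data_off = sf_off + 2u * C;
    if (data_off % 4) data_off += 4 - (data_off % 4);
  }
  const uint32_t nbytes = (uint32_t)(npix * C * 4);
  std::vector<unsigned char> buf;
  buf.reserve(data_off + nbytes);
  buf.push_back('I'); buf.push_back('I'); put_u16le(buf, 42);
  put_u32le(buf, ifd_off);
  put_u16le(buf, ntags);
  tag(buf, 256, 4, 1, (uint32_t)W);                       // ImageWidth
  tag(buf, 257, 4, 1, (uint32_t)H);                       // ImageLength
  tag(buf, 258, 3, (uint32_t)C, C == 1 ? 32u : bps_off);  // BitsPerSample
  tag(buf, 259, 3, 1, 1);                                 // Compression: none
  tag(buf, 262, 3, 1, 1);                                 // Photometric: BlackIsZero
  tag(buf, 273, 4, 1, data_off);                          // StripOffsets
  tag(buf, 277, 3, 1, (uint32_t)C);                       // SamplesPerPixel
  tag(buf, 278, 4, 1, (uint32_t)H);                       // RowsPerStrip
  tag(buf, 279, 4, 1, nbytes);                            // StripByteCounts
  tag(buf, 284, 3, 1, 1);                                 // PlanarConfig: chunky
  tag(buf, 338, 3, C > 1 ? (uint32_t)(C - 1) : 0u, 0u);   // ExtraSamples
  tag(buf, 339, 3, (uint32_t)C, C == 1 ? 3u : sf_off);    // SampleFormat: float
  put_u32le(buf, 0);                                      // next IFD
  if (C > 1) {
    for (int c = 0; c < C; c++) put_u16le(buf, 32);
    for (int c = 0; c < C; c++) put_u16le(buf, 3);
    while (buf.size() < data_off) buf.push_back(0);
  }
  // pixel data: row-major, samples interleaved
  for (int i = 0; i < H; i++)
    for (int j = 0; j < W; j++)
      for (int c = 0; c < C; c++) {
        const double v = arr[(size_t)i + (size_t)j * H + npix * c];
        if (!std::isfinite(v)) stop("non-finite value in field");
        const float fv = (float)v;
        unsigned char b[4];
        std::memcpy(b, &fv, 4);
        buf.insert(buf.end(), b, b + 4);
      }
  FILE* f = fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  fwrite(buf.data(), 1, buf.size(), f);
  fclose(f);
}

static uint16_t rd_u16le(const unsigned char* p) { return p[0] | (p[1] << 8); }
static uint32_t rd_u32le(const unsigned char* p) {
  return p[0] | (p[1] << 8) | ((uint32_t)p[2] << 16) | ((uint32_t)p[3] << 24);
}

// Reads the uncompressed little-endian float TIFF layout written above.
// Returns an H x W x C array.
// [[Rcpp::export]]
NumericVector cpp_read_tiff_float(std::string path) {
  FILE* f = fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  fseek(f, 0, SEEK_END);
  const long fs = ftell(f);
  fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf(fs);
  if (fread(buf.data(), 1, fs, f) != (size_t)fs) { fclose(f); stop("short read on '%s'", path.c_str()); }
  fclose(f);
  if (fs < 8 || buf[0] != 'I' || buf[1] != 'I' || rd_u16le(&buf[2]) != 42)
    stop("'%s' is not a little-endian TIFF", path.c_str());
  const uint32_t ifd = rd_u32le(&buf[4]);
  const uint16_t n = rd_u16le(&buf[ifd]);
  uint32_t W = 0, H = 0, C = 1, strip = 0, comp = 1, sfmt_val = 1, bits_val = 0;
  for (int t = 0; t < n; t++) {
    const unsigned char* e = &buf[ifd + 2 + t * 12];
    const uint16_t id = rd_u16le(e), type = rd_u16le(e + 2);
    const uint32_t count = rd_u32le(e + 4);
    uint32_t val = rd_u32le(e + 8);
    if (type == 3 && count == 1) val = rd_u16le(e + 8);
    switch (id) {
      case 256: W = val; break;
      case 257: H = val; break;
      case 273: strip = val; break;
      case 277: C = val; break;
      case 259: comp = val; break;
      case 258:
        bits_val = (count == 1) ? val : rd_u16le(&buf[val]);
        break;
      case 339:
        sfmt_val = (count == 1) ? val : rd_u16le(&buf[val]);
        break;
    }
  }
  if (comp != 1) stop("compressed TIFF not supported");
  if (bits_val != 32 || sfmt_val != 3)
    stop("'%s' is not a 32-bit float TIFF", path.c_str());
  const size_t npix = (size_t)H * W;
  NumericVector out(npix * C);
  out.attr("dim") = IntegerVector::create((int)H, (int)W, (int)C);
  for (uint32_t i = 0; i < H; i++)
    for (uint32_t j = 0; j < W; j++)
      for (uint32_t c = 0; c < C; c++) {
        float fv;
        std::memcpy(&fv, &buf[strip + 4 * ((((size_t)i * W) + j) * C + c)], 4);
        out[(size_t)i + (size_t)j * H + npix * c] = fv;
      }
  return out;
}
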