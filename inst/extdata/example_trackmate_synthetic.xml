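<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic minimal TrackMate-style model file constructed for examples
     and tests; positions are in micrometres (pixelwidth declared below).
     Track 0 is contiguous over frames 0-4; track 1 contains a gap-closed
     link between frames 2 and 5 and is split at that gap on import. -->
<TrackMate version="7.0.0">
  <Model spatialunits="micron" timeunits="s">
    <AllSpots nspots="13">
      <SpotsInFrame frame="0">
        <Spot ID="1000" FRAME="0" POSITION_X="1.000" POSITION_Y="2.000" POSITION_Z="0" />
        <Spot ID="2000" FRAME="0" POSITION_X="5.000" POSITION_Y="5.000" POSITION_Z="0" />
      </SpotsInFrame>
      <SpotsInFrame frame="1">
        <Spot ID="1001" FRAME="1" POSITION_X="1.050" POSITION_Y="2.010" POSITION_Z="0" />
        <Spot ID="2001" FRAME="1" POSITION_X="5.080" POSITION_Y="4.950" POSITION_Z="0" />
      </SpotsInFrame>
      <SpotsInFrame frame="2">
        <Spot ID="1002" FRAME="2" POSITION_X="1.100" POSITION_Y="2.050" POSITION_Z="0" />
        <Spot ID="2002" FRAME="2" POSITION_X="5.160" POSITION_Y="4.900" POSITION_Z="0" />
      </SpotsInFrame>
      <SpotsInFrame frame="3">
        <Spot ID="1003" FRAME="3" POSITION_X="1.120" POSITION_Y="2.100" POSITION_Z="0" />
      </SpotsInFrame>
      <SpotsInFrame frame="4">
        <Spot ID="1004" FRAME="4" POSITION_X="1.180" POSITION_Y="2.150" POSITION_Z="0" />
      </SpotsInFrame>
      <SpotsInFrame frame="5">
        <Spot ID="2005" FRAME="5" POSITION_X="5.300" POSITION_Y="4.800" POSITION_Z="0" />
      </SpotsInFrame>
      <SpotsInFrame frame="6">
        <Spot ID="2006" FRAME="6" POSITION_X="5.350" POSITION_Y="4.750" POSITION_Z="0" />
        <Spot ID="1006" FRAME="6" POSITION_X="9.000" POSITION_Y="9.000" POSITION_Z="0" />
      </SpotsInFrame>
      <SpotsInFrame frame="7">
        <Spot ID="2007" FRAME="7" POSITION_X="5.400" POSITION_Y="4.700" POSITION_Z="0" />
        <Spot ID="1007" FRAME="7" POSITION_X="9.100" POSITION_Y="9.050" POSITION_Z="0" />
      </SpotsInFrame>
    </AllSpots>
    <AllTracks>
      <Track TRACK_ID="0" NUMBER_SPOTS="5">
        <Edge SPOT_SOURCE_ID="1000" SPOT_TARGET_ID="1001" />
        <Edge SPOT_SOURCE_ID="1001" SPOT_TARGET_ID="1002" />
        <Edge SPOT_SOURCE_ID="1002" SPOT_TARGET_ID="1003" />
        <Edge SPOT_SOURCE_ID="1003" SPOT_TARGET_ID="1004" />
      </Track>
      <Track TRACK_ID="1" NUMBER_SPOTS="6">
        <Edge SPOT_SOURCE_ID="2000" SPOT_TARGET_ID="2001" />
        <Edge SPOT_SOURCE_ID="2001" SPOT_TARGET_ID="2002" />
        <Edge SPOT_SOURCE_ID="2002" SPOT_TARGET_ID="2005" />
        <Edge SPOT_SOURCE_ID="2005" SPOT_TARGET_ID="2006" />
        <Edge SPOT_SOURCE_ID="2006" SPOT_TARGET_ID="2007" />
      </Track>
    </AllTracks>
  </Model>
  <Settings>
    <ImageData filename="synthetic" folder="" width="100" height="100"
               nslices="1" nframes="8" pixelwidth="1.0" pixelheight="1.0"
               voxeldepth="1.0" timeinterval="0.06" />
  </Settings>
</TrackMate>
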