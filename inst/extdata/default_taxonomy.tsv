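# Packaged default activity taxonomy: fine diary codes -> 11 everyday
# domains, with six Exercise and Sport sub-domains after a slash.
activity_code	domain
sleep	Sleep
nap	Sleep
shower	Self-care
grooming	Self-care
dressing	Self-care
eating	Self-care
talk_friends	Social
messaging	Social
phone_call	Social
visiting	Social
art	Cultural
craft	Cultural
museum	Cultural
music_practice	Cultural
tv	Screen Time
video_games	Screen Time
phone_browsing	Screen Time
computer_leisure	Screen Time
house_cleaning	Chores
laundry	Chores
cooking	Chores
gardening	Chores
shopping	Chores
paid_work	Work and Study
study	Work and Study
homework	Work and Study
reading	Quiet Time
meditation	Quiet Time
relaxing	Quiet Time
walk_transport	Active Transport
cycle_transport	Active Transport
car_travel	Passive Transport
bus_travel	Passive Transport
train_travel	Passive Transport
running	Exercise and Sport/Non-Team Sports
swimming	Exercise and Sport/Non-Team Sports
tennis	Exercise and Sport/Non-Team Sports
golf	Exercise and Sport/Non-Team Sports
football	Exercise and Sport/Team Sports
basketball	Exercise and Sport/Team Sports
netball	Exercise and Sport/Team Sports
cricket	Exercise and Sport/Team Sports
weights	Exercise and Sport/Gym
gym_class	Exercise and Sport/Gym
cardio_machine	Exercise and Sport/Gym
dancing	Exercise and Sport/Dance
ballet	Exercise and Sport/Dance
play_pets	Exercise and Sport/Active Play
play_catch	Exercise and Sport/Active Play
playground	Exercise and Sport/Active Play
frisbee	Exercise and Sport/Games
backyard_games	Exercise and Sport/Games
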